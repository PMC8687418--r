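{
  "name": "auto-regulatory gene network (DNA_t = 10)",
  "species": [
    "DNA",
    "P2",
    "mRNA",
    "P"
  ],
  "volume": 1,
  "reactions": [
    {
      "educts": {
        "DNA": 1,
        "P2": 1
      },
      "products": {}
    },
    {
      "educts": {},
      "products": {
        "DNA": 1,
        "P2": 1
      },
      "exponents": {
        "DNA": 1
      },
      "complement_totals": {
        "DNA": 10
      }
    },
    {
      "educts": {
        "DNA": 1
      },
      "products": {
        "DNA": 1,
        "mRNA": 1
      }
    },
    {
      "educts": {
        "mRNA": 1
      },
      "products": {}
    },
    {
      "educts": {
        "P": 2
      },
      "products": {
        "P2": 1
      }
    },
    {
      "educts": {
        "P2": 1
      },
      "products": {
        "P": 2
      }
    },
    {
      "educts": {
        "mRNA": 1
      },
      "products": {
        "mRNA": 1,
        "P": 1
      }
    },
    {
      "educts": {
        "P": 1
      },
      "products": {}
    }
  ]
}
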