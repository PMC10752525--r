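{
  "wide": {
    "mwt": [0, 450],
    "slogp": [-99, 5],
    "hbd": [0, 4],
    "hba": [0, 8],
    "rotb": [0, 8]
  },
  "crude": {
    "mwt": [320, 420],
    "slogp": [0, 4.5],
    "hbd": [0, 3],
    "hba": [0, 8],
    "rotb": [1, 8]
  },
  "agreed": {
    "mwt": [320, 380],
    "slogp": [1, 3],
    "hba": [0, 8],
    "hbd": [0, 3],
    "sfi": [2, 6],
    "rotb": [1, 7]
  }
}
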