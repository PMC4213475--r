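{
  "pathway_id": "fig6",
  "nodes": [
    {
      "id": "ProtA",
      "kind": "single",
      "genes": [
        "gA"
      ]
    },
    {
      "id": "ProtB",
      "kind": "single",
      "genes": [
        "gB"
      ]
    },
    {
      "id": "ProtC",
      "kind": "single",
      "genes": [
        "gC"
      ]
    },
    {
      "id": "ProtD",
      "kind": "single",
      "genes": [
        "gD"
      ]
    },
    {
      "id": "ProtE",
      "kind": "single",
      "genes": [
        "gE"
      ]
    },
    {
      "id": "ProtF",
      "kind": "single",
      "genes": [
        "gF"
      ]
    },
    {
      "id": "ProtG",
      "kind": "single",
      "genes": [
        "gG"
      ]
    },
    {
      "id": "ProtH",
      "kind": "single",
      "genes": [
        "gH"
      ]
    },
    {
      "id": "ProtI",
      "kind": "single",
      "genes": [
        "gI"
      ]
    },
    {
      "id": "ProtJ",
      "kind": "single",
      "genes": [
        "gJ"
      ]
    }
  ],
  "edges": [
    {
      "from": "ProtA",
      "to": "ProtB",
      "sign": "activation"
    },
    {
      "from": "ProtC",
      "to": "ProtB",
      "sign": "activation"
    },
    {
      "from": "ProtB",
      "to": "ProtD",
      "sign": "activation"
    },
    {
      "from": "ProtD",
      "to": "ProtF",
      "sign": "activation"
    },
    {
      "from": "ProtD",
      "to": "ProtG",
      "sign": "activation"
    },
    {
      "from": "ProtF",
      "to": "ProtH",
      "sign": "activation"
    },
    {
      "from": "ProtG",
      "to": "ProtH",
      "sign": "activation"
    },
    {
      "from": "ProtF",
      "to": "ProtI",
      "sign": "activation"
    },
    {
      "from": "ProtE",
      "to": "ProtJ",
      "sign": "activation"
    }
  ]
}
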