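{
  "jurisdiction": "KR",
  "comment": "Synthetic label fixture for the worked example: WHO-ART style preferred terms attributed to each drug's approved Korean label. Not an authoritative label text.",
  "entries": {
    "S01LA05": [
      "endophthalmitis",
      "muscae volitantes",
      "ocular haemorrhage",
      "conjunctival haemorrhage",
      "eye pain",
      "cataract",
      "intraocular pressure increased",
      "visual acuity decreased",
      "retinal detachment"
    ],
    "S01LA04": [
      "retinal disorder",
      "endophthalmitis",
      "retinal detachment",
      "retinal haemorrhage",
      "vision abnormal",
      "conjunctivitis",
      "muscae volitantes",
      "conjunctival haemorrhage",
      "intraocular pressure increased",
      "eye pain",
      "visual acuity decreased"
    ]
  }
}
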