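{
  "jurisdiction": "US",
  "comment": "Synthetic label fixture for the worked example: WHO-ART style preferred terms attributed to each drug's US label. Not an authoritative label text.",
  "entries": {
    "S01LA05": [
      "endophthalmitis",
      "muscae volitantes",
      "ocular haemorrhage",
      "conjunctival haemorrhage",
      "eye pain",
      "cataract",
      "vitreous detachment",
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
      "vitreous floaters",
      "visual acuity decreased"
    ]
  }
}
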