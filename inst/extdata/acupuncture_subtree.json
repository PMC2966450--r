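[
  {
    "name": "Acupuncture Therapy",
    "qualifiers": ["methods", "adverse effects", "instrumentation"],
    "entry_terms": ["acupuncture treatment"],
    "abbreviations": [],
    "supplementary_terms": [],
    "children": [
      {
        "name": "Acupuncture Analgesia",
        "qualifiers": ["methods"],
        "entry_terms": ["acupuncture anesthesia"],
        "children": []
      },
      {
        "name": "Acupuncture, Ear",
        "qualifiers": ["methods"],
        "entry_terms": ["ear acupuncture", "auriculotherapy"],
        "children": []
      },
      {
        "name": "Electroacupuncture",
        "qualifiers": ["methods"],
        "entry_terms": ["electro-acupuncture"],
        "abbreviations": ["EA"],
        "supplementary_terms": ["percutaneous electrical nerve stimulation"],
        "children": []
      },
      {
        "name": "Meridians",
        "qualifiers": [],
        "entry_terms": ["acupuncture meridians"],
        "children": [
          {
            "name": "Acupuncture Points",
            "qualifiers": [],
            "entry_terms": ["acupoints"],
            "children": []
          }
        ]
      },
      {
        "name": "Moxibustion",
        "qualifiers": ["methods"],
        "entry_terms": [],
        "children": []
      }
    ]
  },
  {
    "name": "Attention Deficit Disorder with Hyperactivity",
    "qualifiers": ["therapy", "diagnosis", "drug therapy"],
    "entry_terms": ["adhd", "hyperkinetic syndrome"],
    "children": []
  },
  {
    "name": "Child",
    "qualifiers": ["therapy"],
    "entry_terms": [],
    "children": []
  },
  {
    "name": "Adolescent",
    "qualifiers": [],
    "entry_terms": ["teens"],
    "children": []
  },
  {
    "name": "Pyridoxine",
    "qualifiers": ["administration and dosage", "therapeutic use"],
    "entry_terms": ["vitamin b6", "pyridoxol"],
    "children": []
  }
]
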