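{
  "description": "Default TBI free-text lexicon: canonical clinical terms with synonyms, acronyms and a fixed misspelling-variant table used both by the text search and by the synthetic narrative generator.",
  "negation_cues": ["no", "not", "without", "denies", "denied", "nil", "excluded", "absent"],
  "entries": [
    {
      "canonical_term": "subdural haematoma",
      "category": "pathology",
      "pathology_code": "SDH",
      "synonyms": ["subdural hematoma", "subdural haemorrhage", "subdural hemorrhage", "acute subdural", "subdural bleed"],
      "acronyms": ["SDH"],
      "misspellings": ["subdurral haematoma", "subdual haematoma"]
    },
    {
      "canonical_term": "subarachnoid haemorrhage",
      "category": "pathology",
      "pathology_code": "SAH",
      "synonyms": ["subarachnoid hemorrhage", "subarachnoid bleed", "subarachnoid blood"],
      "acronyms": ["SAH"],
      "misspellings": ["subarachnoid haemorrage", "subarachniod haemorrhage"]
    },
    {
      "canonical_term": "extradural haematoma",
      "category": "pathology",
      "pathology_code": "EDH",
      "synonyms": ["epidural haematoma", "epidural hematoma", "extradural haemorrhage", "extradural bleed"],
      "acronyms": ["EDH"],
      "misspellings": ["extradurral haematoma", "extradual haematoma"]
    },
    {
      "canonical_term": "cerebral contusion",
      "category": "pathology",
      "pathology_code": "focal",
      "synonyms": ["brain contusion", "contusion", "focal brain injury", "intracerebral haemorrhage", "intracerebral hemorrhage", "intraparenchymal haemorrhage"],
      "acronyms": ["ICH"],
      "misspellings": ["cerebral contussion", "cerebral contusoin"]
    },
    {
      "canonical_term": "diffuse axonal injury",
      "category": "pathology",
      "pathology_code": "DAI",
      "synonyms": ["axonal shear injury", "shear injury to white matter"],
      "acronyms": ["DAI"],
      "misspellings": ["diffuse axonal injry", "difuse axonal injury"]
    },
    {
      "canonical_term": "skull fracture",
      "category": "pathology",
      "pathology_code": "skull_fracture",
      "synonyms": ["fractured skull", "fracture of the skull", "basilar skull fracture", "base of skull fracture", "depressed skull fracture", "linear skull fracture", "vault fracture"],
      "acronyms": ["BOS fracture"],
      "misspellings": ["skull fractre", "skull farcture"]
    },
    {
      "canonical_term": "headache",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["head ache", "cephalgia"],
      "acronyms": [],
      "misspellings": ["headach"]
    },
    {
      "canonical_term": "confusion",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["confused", "disorientated", "disoriented"],
      "acronyms": [],
      "misspellings": ["confusoin"]
    },
    {
      "canonical_term": "dizziness",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["dizzy", "vertigo"],
      "acronyms": [],
      "misspellings": ["dizzines"]
    },
    {
      "canonical_term": "nausea",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["nauseated", "vomiting"],
      "acronyms": [],
      "misspellings": ["nausae"]
    },
    {
      "canonical_term": "blurred vision",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["blurry vision", "visual blurring"],
      "acronyms": [],
      "misspellings": ["blured vision"]
    },
    {
      "canonical_term": "dazed",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["stunned", "groggy"],
      "acronyms": [],
      "misspellings": ["dazzed"]
    },
    {
      "canonical_term": "focal neurological signs",
      "category": "symptom",
      "pathology_code": "none",
      "synonyms": ["focal neurology", "focal neurological deficit", "hemiparesis", "unilateral weakness"],
      "acronyms": [],
      "misspellings": ["focal neurologcal signs"]
    },
    {
      "canonical_term": "craniotomy",
      "category": "treatment",
      "pathology_code": "none",
      "synonyms": ["burr hole evacuation"],
      "acronyms": [],
      "misspellings": ["crainotomy"]
    },
    {
      "canonical_term": "craniectomy",
      "category": "treatment",
      "pathology_code": "none",
      "synonyms": ["decompressive craniectomy"],
      "acronyms": [],
      "misspellings": ["craniectmy"]
    },
    {
      "canonical_term": "intracranial pressure monitor",
      "category": "treatment",
      "pathology_code": "none",
      "synonyms": ["intracranial pressure bolt"],
      "acronyms": ["ICP monitor"],
      "misspellings": []
    },
    {
      "canonical_term": "loss of consciousness",
      "category": "indicator",
      "pathology_code": "none",
      "synonyms": ["knocked out", "unconscious"],
      "acronyms": ["LOC"],
      "misspellings": ["loss of conciousness"]
    },
    {
      "canonical_term": "post-traumatic amnesia",
      "category": "indicator",
      "pathology_code": "none",
      "synonyms": ["amnesia for events"],
      "acronyms": ["PTA"],
      "misspellings": ["post traumatic amnsia"]
    }
  ]
}
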