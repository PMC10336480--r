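{
  "version": 1,
  "comment": "Guideline-style rule table: (sublocation, stage class) -> candidate regimens before feasibility filtering. Regimen order is treatment sequence (surgery first = surgery with adjuvant therapy). Cells with anchored=true are pinned to a published reference decision; unanchored cells follow the table's general pattern (advanced non-nasopharyngeal disease: surgery+adjuvant radiation or concurrent chemoradiation; nasopharynx never surgical).",
  "entries": [
    {"site": "larynx_glottic", "stage": "early",
     "regimens": [["radiation"], ["surgery"]], "anchored": true},
    {"site": "larynx_glottic", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": false},
    {"site": "larynx_supraglottic", "stage": "early",
     "regimens": [["surgery", "radiation"], ["radiation"]], "anchored": true},
    {"site": "larynx_supraglottic", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": false},
    {"site": "nasopharynx", "stage": "early",
     "regimens": [["radiation", "chemotherapy"]], "anchored": true},
    {"site": "nasopharynx", "stage": "locally_advanced",
     "regimens": [["radiation", "chemotherapy"]], "anchored": true},
    {"site": "oral_tongue", "stage": "early",
     "regimens": [["surgery"], ["radiation"]], "anchored": true},
    {"site": "oral_tongue", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": false},
    {"site": "floor_of_mouth", "stage": "early",
     "regimens": [["surgery"], ["radiation"]], "anchored": false},
    {"site": "floor_of_mouth", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true},
    {"site": "oropharynx", "stage": "early",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true},
    {"site": "oropharynx", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true},
    {"site": "tongue_base", "stage": "early",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": false},
    {"site": "tongue_base", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true},
    {"site": "hypopharynx", "stage": "early",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true},
    {"site": "hypopharynx", "stage": "locally_advanced",
     "regimens": [["surgery", "radiation"], ["radiation", "chemotherapy"]], "anchored": true}
  ]
}
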