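{
  "@context": "https://github.com/larisa-soldatova/HELO",
  "schema_version": "1.0",
  "entities": [
    {
      "id": "ARO1",
      "label": "ARO1",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "aaa_mutant_strain",
      "label": "AAA pathway deletion mutant",
      "helo_class": "entity"
    },
    {
      "id": "ARO2",
      "label": "ARO2",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "ARO3",
      "label": "ARO3",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "ARO4",
      "label": "ARO4",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "ARO7",
      "label": "ARO7",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "TRP2",
      "label": "TRP2",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "TYR1",
      "label": "TYR1",
      "source_ontology": "SGD",
      "helo_class": "entity"
    },
    {
      "id": "PHA2",
      "label": "PHA2",
      "source_ontology": "SGD",
      "helo_class": "entity"
    }
  ],
  "statements": [
    {
      "id": "aaa_h_ARO1",
      "role": "research_hypothesis",
      "expression": "deleted(ARO1, aaa_mutant_strain)",
      "free_text": "The gene ARO1 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_ARO2",
      "role": "research_hypothesis",
      "expression": "deleted(ARO2, aaa_mutant_strain)",
      "free_text": "The gene ARO2 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_ARO3",
      "role": "research_hypothesis",
      "expression": "deleted(ARO3, aaa_mutant_strain)",
      "free_text": "The gene ARO3 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_ARO4",
      "role": "research_hypothesis",
      "expression": "deleted(ARO4, aaa_mutant_strain)",
      "free_text": "The gene ARO4 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_ARO7",
      "role": "research_hypothesis",
      "expression": "deleted(ARO7, aaa_mutant_strain)",
      "free_text": "The gene ARO7 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_TRP2",
      "role": "research_hypothesis",
      "expression": "deleted(TRP2, aaa_mutant_strain)",
      "free_text": "The gene TRP2 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_TYR1",
      "role": "research_hypothesis",
      "expression": "deleted(TYR1, aaa_mutant_strain)",
      "free_text": "The gene TYR1 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "aaa_h_PHA2",
      "role": "research_hypothesis",
      "expression": "deleted(PHA2, aaa_mutant_strain)",
      "free_text": "The gene PHA2 has been deleted from the mutant strain.",
      "helo_class": "research hypothesis"
    }
  ],
  "evidence": [],
  "links": [],
  "homology_links": [],
  "probability_records": [
    {
      "statement_id": "aaa_h_ARO1",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_ARO2",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_ARO3",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_ARO4",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_ARO7",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_TRP2",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_TYR1",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    },
    {
      "statement_id": "aaa_h_PHA2",
      "value": 0.125,
      "kind": "prior",
      "method": "abduction",
      "procedure": "uniform prior over the abduced hypothesis set",
      "timestamp": "2009-01-01",
      "helo_class": "prior probability",
      "estimation_class": "abduction"
    }
  ],
  "hypothesis_sets": {
    "aaa": {
      "id": "aaa",
      "members": [
        "aaa_h_ARO1",
        "aaa_h_ARO2",
        "aaa_h_ARO3",
        "aaa_h_ARO4",
        "aaa_h_ARO7",
        "aaa_h_TRP2",
        "aaa_h_TYR1",
        "aaa_h_PHA2"
      ],
      "probs": [
        0.125,
        0.125,
        0.125,
        0.125,
        0.125,
        0.125,
        0.125,
        0.125
      ],
      "helo_class": "hypotheses set"
    }
  }
}
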