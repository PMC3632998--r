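{
  "@context": "https://github.com/larisa-soldatova/HELO",
  "schema_version": "1.0",
  "entities": [
    {
      "id": "SIRT1",
      "label": "SIRT1",
      "helo_class": "entity"
    },
    {
      "id": "human_life_span",
      "label": "human_life_span",
      "helo_class": "entity"
    },
    {
      "id": "sir-2.1",
      "label": "sir-2.1",
      "helo_class": "entity"
    },
    {
      "id": "nematode_life_span",
      "label": "nematode_life_span",
      "helo_class": "entity"
    },
    {
      "id": "SIR2",
      "label": "SIR2",
      "helo_class": "entity"
    },
    {
      "id": "yeast_life_span",
      "label": "yeast_life_span",
      "helo_class": "entity"
    },
    {
      "id": "Sirt6",
      "label": "Sirt6",
      "helo_class": "entity"
    },
    {
      "id": "mouse_life_span",
      "label": "mouse_life_span",
      "helo_class": "entity"
    }
  ],
  "statements": [
    {
      "id": "h1",
      "role": "research_hypothesis",
      "expression": "regulates(SIRT1, human_life_span)",
      "free_text": "SIRT1 regulates life span in Homo sapiens.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "h2",
      "role": "research_hypothesis",
      "expression": "regulates(sir-2.1, nematode_life_span)",
      "free_text": "sir-2.1 regulates life span in Caenorhabditis elegans.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "h3",
      "role": "research_hypothesis",
      "expression": "regulates(SIR2, yeast_life_span)",
      "free_text": "SIR2 regulates life span in Saccharomyces cerevisiae.",
      "helo_class": "research hypothesis"
    },
    {
      "id": "h4",
      "role": "research_hypothesis",
      "expression": "regulates(Sirt6, mouse_life_span)",
      "free_text": "Sirt6 regulates life span in Mus musculus.",
      "helo_class": "research hypothesis"
    }
  ],
  "evidence": [
    {
      "id": "tissenbaum_guarente_2001",
      "description": "Increased dosage of the SIRT1 homolog extends lifespan in C. elegans.",
      "source_type": "publication",
      "date": "2001-03-08",
      "helo_class": "evidence"
    },
    {
      "id": "yeast70_literature_counts",
      "description": "Literature-mining counts: SIR2 dominates aging-related yeast gene mentions.",
      "source_type": "database",
      "date": "2010-06-01",
      "helo_class": "evidence"
    },
    {
      "id": "burnett_2011",
      "description": "Overexpressing the sirtuin gene in C. elegans and D. melanogaster did not boost longevity.",
      "source_type": "publication",
      "date": "2011-09-22",
      "helo_class": "evidence"
    },
    {
      "id": "kanfi_2012",
      "description": "The sirtuin Sirt6 regulates lifespan in male mice.",
      "source_type": "publication",
      "date": "2012-02-23",
      "helo_class": "evidence"
    }
  ],
  "links": [
    {
      "statement_id": "h2",
      "evidence_id": "tissenbaum_guarente_2001",
      "relation": "supports",
      "helo_class": "HAS-SUPPORTING-EVIDENCE"
    },
    {
      "statement_id": "h1",
      "evidence_id": "tissenbaum_guarente_2001",
      "relation": "supports",
      "helo_class": "HAS-SUPPORTING-EVIDENCE"
    },
    {
      "statement_id": "h3",
      "evidence_id": "yeast70_literature_counts",
      "relation": "supports",
      "helo_class": "HAS-SUPPORTING-EVIDENCE"
    },
    {
      "statement_id": "h2",
      "evidence_id": "burnett_2011",
      "relation": "refutes",
      "helo_class": "HAS-REFUTING-EVIDENCE"
    },
    {
      "statement_id": "h1",
      "evidence_id": "burnett_2011",
      "relation": "refutes",
      "helo_class": "HAS-REFUTING-EVIDENCE"
    },
    {
      "statement_id": "h4",
      "evidence_id": "kanfi_2012",
      "relation": "supports",
      "helo_class": "HAS-SUPPORTING-EVIDENCE"
    },
    {
      "statement_id": "h1",
      "evidence_id": "kanfi_2012",
      "relation": "supports",
      "helo_class": "HAS-SUPPORTING-EVIDENCE"
    }
  ],
  "homology_links": [
    {
      "source_id": "h2",
      "target_id": "h1",
      "weight": 0.5,
      "helo_class": "homological inference"
    },
    {
      "source_id": "h3",
      "target_id": "h1",
      "weight": 0.5,
      "helo_class": "homological inference"
    },
    {
      "source_id": "h4",
      "target_id": "h1",
      "weight": 0.5,
      "helo_class": "homological inference"
    }
  ],
  "probability_records": [
    {
      "statement_id": "h1",
      "value": 0.5,
      "kind": "prior",
      "method": "expert_estimation",
      "timestamp": "2000-01-01",
      "helo_class": "prior probability",
      "estimation_class": "expert estimation"
    },
    {
      "statement_id": "h2",
      "value": 0.6,
      "kind": "prior",
      "method": "expert_estimation",
      "timestamp": "2000-01-01",
      "helo_class": "prior probability",
      "estimation_class": "expert estimation"
    },
    {
      "statement_id": "h3",
      "value": 0.9,
      "kind": "prior",
      "method": "expert_estimation",
      "timestamp": "2000-01-01",
      "helo_class": "prior probability",
      "estimation_class": "expert estimation"
    },
    {
      "statement_id": "h4",
      "value": 0.5,
      "kind": "prior",
      "method": "expert_estimation",
      "timestamp": "2000-01-01",
      "helo_class": "prior probability",
      "estimation_class": "expert estimation"
    },
    {
      "statement_id": "h2",
      "value": 0.85,
      "kind": "posterior",
      "method": "bayesian_inference",
      "timestamp": "2001-03-08",
      "source": "tissenbaum_guarente_2001",
      "helo_class": "posterior probability",
      "estimation_class": "Bayesian inference"
    },
    {
      "statement_id": "h1",
      "value": 0.8,
      "kind": "posterior",
      "method": "expert_estimation",
      "timestamp": "2001-03-08",
      "source": "tissenbaum_guarente_2001",
      "helo_class": "posterior probability",
      "estimation_class": "expert estimation"
    },
    {
      "statement_id": "h3",
      "value": 0.97,
      "kind": "posterior",
      "method": "statistical_calculation",
      "procedure": "aging-sentence keyword counts over a literature database",
      "timestamp": "2010-06-01",
      "source": "yeast70_literature_counts",
      "helo_class": "posterior probability",
      "estimation_class": "statistical calculation"
    },
    {
      "statement_id": "h2",
      "value": 0.35,
      "kind": "posterior",
      "method": "bayesian_inference",
      "timestamp": "2011-09-22",
      "source": "burnett_2011",
      "helo_class": "posterior probability",
      "estimation_class": "Bayesian inference"
    },
    {
      "statement_id": "h1",
      "value": 0.55,
      "kind": "posterior",
      "method": "homological_inference",
      "procedure": "linear transfer, weight 0.5, from h2",
      "timestamp": "2011-09-22",
      "source": "burnett_2011",
      "helo_class": "posterior probability",
      "estimation_class": "homological inference"
    },
    {
      "statement_id": "h4",
      "value": 0.8,
      "kind": "posterior",
      "method": "bayesian_inference",
      "timestamp": "2012-02-23",
      "source": "kanfi_2012",
      "helo_class": "posterior probability",
      "estimation_class": "Bayesian inference"
    },
    {
      "statement_id": "h1",
      "value": 0.7,
      "kind": "posterior",
      "method": "homological_inference",
      "procedure": "linear transfer, weight 0.5, from h4",
      "timestamp": "2012-02-23",
      "source": "kanfi_2012",
      "helo_class": "posterior probability",
      "estimation_class": "homological inference"
    }
  ],
  "hypothesis_sets": []
}
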