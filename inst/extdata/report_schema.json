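{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "lipidpanel patient report",
  "type": "object",
  "required": ["sample_id", "referral_phenotype", "report_category", "rare_variant_findings", "disclosed_score", "notes"],
  "properties": {
    "sample_id": {
      "type": "string"
    },
    "referral_phenotype": {
      "type": "string"
    },
    "report_category": {
      "type": "string",
      "enum": ["a_diagnosis", "b_confirmation", "c_relevant", "d_negative"]
    },
    "diagnosis": {
      "type": ["string", "null"]
    },
    "rare_variant_findings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "description", "zygosity", "kind"],
        "properties": {
          "gene": {
            "type": "string"
          },
          "description": {
            "type": "string"
          },
          "zygosity": {
            "enum": ["heterozygous", "homozygous"]
          },
          "kind": {
            "enum": ["SNV/indel", "CNV"]
          }
        }
      }
    },
    "disclosed_score": {
      "type": "object",
      "required": ["trait", "raw_score", "allele_tally", "n_snps_used", "percentile", "extreme"],
      "properties": {
        "trait": {
          "enum": ["LDL", "TG", "HDL"]
        },
        "raw_score": {
          "type": "number"
        },
        "allele_tally": {
          "type": "integer"
        },
        "n_snps_used": {
          "type": "integer"
        },
        "percentile": {
          "type": "number"
        },
        "extreme": {
          "type": "boolean"
        }
      }
    },
    "notes": {
      "type": "string"
    }
  }
}
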