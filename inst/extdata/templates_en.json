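{
  "language": "en",
  "templates": [
    {
      "id": "en_full",
      "sentences": [
        {
          "pattern": "A {method} identified the variant {cdna} ({dbsnp}) in the {gene} gene in a {zygosity} state.",
          "slots": {"method": "DIAGNOSTIC_METHOD", "cdna": "CDNA_PROT", "dbsnp": "DBSNP_ID", "gene": "GENE", "zygosity": "ZYGOSITY"},
          "optional": false
        },
        {
          "pattern": "Per ACMG/AMP criteria the variant is classified as {significance} (ClinVar: {clinvar}).",
          "slots": {"significance": "SIGNIFICANCE", "clinvar": "CLINVAR_ID"},
          "optional": false
        },
        {
          "pattern": "Pathogenic variants in {gene_b} are associated with {disease} ({omim}); inheritance is {inheritance}.",
          "slots": {"gene_b": "GENE", "disease": "DISEASE", "omim": "OMIM_ID", "inheritance": "INHERITANCE_MODE"},
          "optional": false
        },
        {
          "pattern": "The patient's phenotype ({phenotype}) is consistent with this disease.",
          "slots": {"phenotype": "PHENOTYPE"},
          "optional": true
        },
        {
          "pattern": "The variant affects {exon} of the {gene_c} gene; genomic coordinate — {gloc}.",
          "slots": {"exon": "EXON_NUMBER", "gene_c": "GENE", "gloc": "VARIANT_LOC"},
          "optional": true
        },
        {
          "pattern": "Protein-level change: {prot}.",
          "slots": {"prot": "CDNA_PROT"},
          "optional": true
        },
        {
          "pattern": "{recommendation}.",
          "slots": {"recommendation": "RECOMMENDATION"},
          "optional": true
        },
        {
          "pattern": "{retest}.",
          "slots": {"retest": "RETEST_PLAN"},
          "optional": true
        },
        {
          "pattern": "{therapy}.",
          "slots": {"therapy": "THERAPY_RECOMMENDATION"},
          "optional": true
        }
      ],
      "relations": [
        ["VARIANT_IN_GENE", "cdna", "gene"],
        ["VARIANT_ZYGOSITY", "cdna", "zygosity"],
        ["VARIANT_SIGNIFICANCE", "cdna", "significance"],
        ["GENE_ASSOCIATED_WITH", "gene_b", "disease"],
        ["DISEASE_OMIM_ID", "disease", "omim"],
        ["DISEASE_INHERITANCE_MODE", "disease", "inheritance"],
        ["PHENOTYPE_SUPPORTS_DISEASE", "phenotype", "disease"],
        ["VARIANT_IN_GENE", "gloc", "gene_c"]
      ],
      "parents": [
        ["method", "cdna"],
        ["dbsnp", "gene"],
        ["omim", "disease"],
        ["inheritance", "disease"],
        ["phenotype", "disease"],
        ["exon", "gene_c"],
        ["recommendation", "gene"],
        ["retest", "gene"],
        ["therapy", "disease"]
      ]
    },
    {
      "id": "en_minimal",
      "sentences": [
        {
          "pattern": "Mutation {cdna} in {gene}.",
          "slots": {"cdna": "CDNA_PROT", "gene": "GENE"},
          "optional": false
        }
      ],
      "relations": [
        ["VARIANT_IN_GENE", "cdna", "gene"]
      ],
      "parents": [
        ["cdna", "gene"]
      ]
    }
  ]
}
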