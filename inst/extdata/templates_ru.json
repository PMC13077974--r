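{
  "language": "ru",
  "templates": [
    {
      "id": "ru_full",
      "sentences": [
        {
          "pattern": "Методом {method} в гене {gene} выявлен вариант {cdna} ({dbsnp}) в состоянии {zygosity}.",
          "slots": {"method": "DIAGNOSTIC_METHOD", "gene": "GENE", "cdna": "CDNA_PROT", "dbsnp": "DBSNP_ID", "zygosity": "ZYGOSITY"},
          "optional": false
        },
        {
          "pattern": "Согласно критериям ACMG/AMP вариант классифицирован как {significance} (ClinVar: {clinvar}).",
          "slots": {"significance": "SIGNIFICANCE", "clinvar": "CLINVAR_ID"},
          "optional": false
        },
        {
          "pattern": "Патогенные варианты в гене {gene_b} ассоциированы с заболеванием {disease} ({omim}); тип наследования — {inheritance}.",
          "slots": {"gene_b": "GENE", "disease": "DISEASE", "omim": "OMIM_ID", "inheritance": "INHERITANCE_MODE"},
          "optional": false
        },
        {
          "pattern": "Выявленный у пациента фенотип ({phenotype}) согласуется с указанным заболеванием.",
          "slots": {"phenotype": "PHENOTYPE"},
          "optional": true
        },
        {
          "pattern": "Локализация варианта: {exon} гена {gene_c}; геномная координата — {gloc}.",
          "slots": {"exon": "EXON_NUMBER", "gene_c": "GENE", "gloc": "VARIANT_LOC"},
          "optional": true
        },
        {
          "pattern": "Изменение на уровне белка: {prot}.",
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
        ["zygosity", "gene"],
        ["clinvar", "gene"],
        ["significance", "gene"],
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
      "id": "ru_standard",
      "sentences": [
        {
          "pattern": "В гене {gene} обнаружен вариант {cdna} в состоянии {zygosity}.",
          "slots": {"gene": "GENE", "cdna": "CDNA_PROT", "zygosity": "ZYGOSITY"},
          "optional": false
        },
        {
          "pattern": "Клиническая значимость варианта: {significance}.",
          "slots": {"significance": "SIGNIFICANCE"},
          "optional": false
        },
        {
          "pattern": "Ген {gene_b} ассоциирован с заболеванием {disease}; наследование — {inheritance}.",
          "slots": {"gene_b": "GENE", "disease": "DISEASE", "inheritance": "INHERITANCE_MODE"},
          "optional": true
        },
        {
          "pattern": "{recommendation}.",
          "slots": {"recommendation": "RECOMMENDATION"},
          "optional": true
        }
      ],
      "relations": [
        ["VARIANT_IN_GENE", "cdna", "gene"],
        ["VARIANT_ZYGOSITY", "cdna", "zygosity"],
        ["VARIANT_SIGNIFICANCE", "cdna", "significance"],
        ["GENE_ASSOCIATED_WITH", "gene_b", "disease"],
        ["DISEASE_INHERITANCE_MODE", "disease", "inheritance"]
      ],
      "parents": [
        ["zygosity", "gene"],
        ["significance", "gene"],
        ["inheritance", "disease"],
        ["recommendation", "gene"]
      ]
    },
    {
      "id": "ru_genomic",
      "sentences": [
        {
          "pattern": "При анализе данных секвенирования выявлен вариант {gloc} в гене {gene}.",
          "slots": {"gloc": "VARIANT_LOC", "gene": "GENE"},
          "optional": false
        },
        {
          "pattern": "Клиническая значимость варианта: {significance}.",
          "slots": {"significance": "SIGNIFICANCE"},
          "optional": false
        },
        {
          "pattern": "Фенотип пациента ({phenotype}) согласуется с заболеванием {disease}.",
          "slots": {"phenotype": "PHENOTYPE", "disease": "DISEASE"},
          "optional": true
        },
        {
          "pattern": "{recommendation}.",
          "slots": {"recommendation": "RECOMMENDATION"},
          "optional": true
        }
      ],
      "relations": [
        ["VARIANT_IN_GENE", "gloc", "gene"],
        ["VARIANT_SIGNIFICANCE", "gloc", "significance"],
        ["PHENOTYPE_SUPPORTS_DISEASE", "phenotype", "disease"]
      ],
      "parents": [
        ["significance", "gene"],
        ["phenotype", "disease"],
        ["recommendation", "gene"]
      ]
    },
    {
      "id": "ru_minimal",
      "sentences": [
        {
          "pattern": "Выявлен вариант {cdna} в гене {gene}.",
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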