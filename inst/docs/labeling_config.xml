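<!-- Static Label Studio labeling-config example for the 16-type scheme.
     Paste into a Label Studio project's Labeling Interface. -->
<View>
  <Labels name="label" toName="text">
    <Label value="GENE"/>
    <Label value="CDNA_PROT"/>
    <Label value="VARIANT_LOC"/>
    <Label value="DISEASE"/>
    <Label value="SIGNIFICANCE"/>
    <Label value="ZYGOSITY"/>
    <Label value="INHERITANCE_MODE"/>
    <Label value="OMIM_ID"/>
    <Label value="CLINVAR_ID"/>
    <Label value="DBSNP_ID"/>
    <Label value="PHENOTYPE"/>
    <Label value="RECOMMENDATION"/>
    <Label value="EXON_NUMBER"/>
    <Label value="DIAGNOSTIC_METHOD"/>
    <Label value="RETEST_PLAN"/>
    <Label value="THERAPY_RECOMMENDATION"/>
  </Labels>
  <Relations>
    <Relation value="VARIANT_IN_GENE"/>
    <Relation value="GENE_ASSOCIATED_WITH"/>
    <Relation value="VARIANT_SIGNIFICANCE"/>
    <Relation value="DISEASE_INHERITANCE_MODE"/>
    <Relation value="PHENOTYPE_SUPPORTS_DISEASE"/>
    <Relation value="DISEASE_OMIM_ID"/>
    <Relation value="VARIANT_ZYGOSITY"/>
  </Relations>
  <Text name="text" value="$text"/>
</View>
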