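<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic 5-reaction SBML fixture (fbc gene associations) for testing
     reaction scoring. Not derived from any published model. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_hepatocyte_synthetic" fbc:strict="false">
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_ACLY" fbc:label="ACLY"/>
      <fbc:geneProduct fbc:id="G_FASN" fbc:label="FASN"/>
      <fbc:geneProduct fbc:id="G_GCK" fbc:label="GCK"/>
      <fbc:geneProduct fbc:id="G_G6PC" fbc:label="G6PC"/>
      <fbc:geneProduct fbc:id="G_PYGL" fbc:label="PYGL"/>
      <fbc:geneProduct fbc:id="G_SCD" fbc:label="SCD"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_GLCK" reversible="false">
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_GCK"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_FA_SYN" reversible="false">
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_ACLY"/>
            <fbc:geneProductRef fbc:geneProduct="G_FASN"/>
            <fbc:geneProductRef fbc:geneProduct="G_SCD"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_FA_SYN_ER" reversible="false">
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_ACLY"/>
            <fbc:geneProductRef fbc:geneProduct="G_FASN"/>
            <fbc:geneProductRef fbc:geneProduct="G_SCD"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_G6PASE" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: G6PC</p>
          </body>
        </notes>
      </reaction>
      <reaction id="R_TRANSPORT" reversible="true">
      </reaction>
    </listOfReactions>
  </model>
</sbml>
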