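<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="model" fbc:strict="false">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="A_ext" name="A (medium)" compartment="e" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B" name="metabolite B" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B_ext" name="B (medium)" compartment="e" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r_AtoB" reversible="false" fast="false">
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="gene1"/>
              <fbc:geneProductRef fbc:geneProduct="gene2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="gene3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r_Auptake" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="A_ext" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r_Bexport" reversible="false" fast="false">
        <fbc:geneProductAssociation>
            <fbc:geneProductRef fbc:geneProduct="gene4"/>
        </fbc:geneProductAssociation>
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_ext" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
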