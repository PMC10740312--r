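<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="model" fbc:strict="true">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfParameters>
      <parameter id="bnd_1" value="-1000" constant="true"/>
      <parameter id="bnd_2" value="0" constant="true"/>
      <parameter id="bnd_3" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="M_A1" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_B1" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="X" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="R"/>
      <species id="glc_e" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="C6H12O6"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g_A1" fbc:label="g_A1"/>
      <fbc:geneProduct fbc:id="G_g_A2" fbc:label="g_A2"/>
      <fbc:geneProduct fbc:id="G_g_B1" fbc:label="g_B1"/>
      <fbc:geneProduct fbc:id="G_g_B2" fbc:label="g_B2"/>
      <fbc:geneProduct fbc:id="G_g_bio" fbc:label="g_bio"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Exchange</p></body></notes>
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="P_A1" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Pathway A</p></body></notes>
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_A1" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_A1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="P_A2" reversible="true" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Pathway A</p></body></notes>
        <listOfReactants>
          <speciesReference species="M_A1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_A2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="P_B1" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Pathway B</p></body></notes>
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B1" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_B1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="P_B2" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Pathway B</p></body></notes>
        <listOfReactants>
          <speciesReference species="M_B1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_B2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: Biomass</p></body></notes>
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_bio"/>
        </fbc:geneProductAssociation>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>
  </model>
</sbml>
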