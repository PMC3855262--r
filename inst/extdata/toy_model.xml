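<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_c" name="metabolite A" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="B_c" name="metabolite B" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="C_c" name="metabolite C" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="D_c" name="metabolite D" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_neg10" value="-10" constant="true"/>
      <parameter id="lb_neg1000" value="-1000" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" name="A exchange" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_neg10" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R1" name="A to B" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R2" name="B to C" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_neg1000" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g2"/>
            <fbc:geneProductRef fbc:geneProduct="g3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R3" name="B and C to D" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="g2"/>
            <fbc:geneProductRef fbc:geneProduct="g3"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="BIOMASS_toy" name="toy biomass" reversible="false"
                fast="false" fbc:lowerFluxBound="lb_zero"
                fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="C_c" stoichiometry="0.5" constant="true"/>
          <speciesReference species="D_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
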