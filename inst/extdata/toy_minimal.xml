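<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" xmlns:html="http://www.w3.org/1999/xhtml" level="2" version="1">
  <model id="TOY1_seed1">
    <listOfCompartments>
      <compartment id="c" name="cytosol"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_c" name="substrate" compartment="c"/>
      <species id="B_c" name="precursor" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" name="A uptake" reversible="false">
        <notes><html:body>
          <html:p>GENE_ASSOCIATION: </html:p>
          <html:p>SUBSYSTEM: exchange</html:p>
        </html:body></notes>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="               1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="               0" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="              10" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="               0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R1" name="route 1" reversible="false">
        <notes><html:body>
          <html:p>GENE_ASSOCIATION: </html:p>
          <html:p>SUBSYSTEM: core</html:p>
        </html:body></notes>
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="               1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="               1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="               0" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="INF" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="               0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R2" name="route 2" reversible="false">
        <notes><html:body>
          <html:p>GENE_ASSOCIATION: </html:p>
          <html:p>SUBSYSTEM: core</html:p>
        </html:body></notes>
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="               1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="               1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="               0" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="INF" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="               0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="BIO" name="biomass drain" reversible="false">
        <notes><html:body>
          <html:p>GENE_ASSOCIATION: </html:p>
          <html:p>SUBSYSTEM: biomass</html:p>
        </html:body></notes>
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="               1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="               0" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="INF" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="               1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
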