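<?xml version="1.0" encoding="UTF-8"?>
<molecularModel>
  <listOfSpecies>
    <species id="proliferation" name="proliferation" kind="pseudo-object" compartment="cytoplasm" initialConcentration="0"/>
    <species id="ENSG00000000001" name="G1" kind="gene" compartment="nucleus" initialConcentration="0"/>
    <species id="mRNA:ENSG00000000001" name="mRNA:ENSG00000000001" kind="mRNA" compartment="cytoplasm" initialConcentration="0"/>
    <species id="prot:ENSG00000000001" name="MTOR" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="ENSG00000000002" name="G2" kind="gene" compartment="nucleus" initialConcentration="0"/>
    <species id="mRNA:ENSG00000000002" name="mRNA:ENSG00000000002" kind="mRNA" compartment="cytoplasm" initialConcentration="0"/>
    <species id="prot:ENSG00000000002" name="P2" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="pprot:ENSG00000000002" name="P-P2" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="ENSG00000000003" name="G3" kind="gene" compartment="nucleus" initialConcentration="0"/>
    <species id="mRNA:ENSG00000000003" name="mRNA:ENSG00000000003" kind="mRNA" compartment="cytoplasm" initialConcentration="0"/>
    <species id="prot:ENSG00000000003" name="P3" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="pprot:ENSG00000000003" name="P-P3" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="ENSG00000000004" name="G4" kind="gene" compartment="nucleus" initialConcentration="0"/>
    <species id="mRNA:ENSG00000000004" name="mRNA:ENSG00000000004" kind="mRNA" compartment="cytoplasm" initialConcentration="0"/>
    <species id="prot:ENSG00000000004" name="P4" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
    <species id="ENSG00000000005" name="G5" kind="gene" compartment="nucleus" initialConcentration="0"/>
    <species id="mRNA:ENSG00000000005" name="mRNA:ENSG00000000005" kind="mRNA" compartment="cytoplasm" initialConcentration="0"/>
    <species id="prot:ENSG00000000005" name="P5" kind="protein" compartment="cytoplasm" initialConcentration="0"/>
  </listOfSpecies>
  <listOfReactions>
    <reaction id="act:ENSG00000000002" rtype="activation" k="0.002">
      <product ref="proliferation"/>
      <enzyme ref="pprot:ENSG00000000002"/>
    </reaction>
    <reaction id="act:ENSG00000000003" rtype="activation" k="0.002">
      <product ref="proliferation"/>
      <enzyme ref="pprot:ENSG00000000003"/>
    </reaction>
    <reaction id="act:ENSG00000000004" rtype="activation" k="0.002">
      <product ref="proliferation"/>
      <enzyme ref="prot:ENSG00000000004"/>
    </reaction>
    <reaction id="act:ENSG00000000005" rtype="activation" k="0.002">
      <product ref="proliferation"/>
      <enzyme ref="prot:ENSG00000000005"/>
    </reaction>
    <reaction id="dec:mRNA:ENSG00000000001" rtype="decay" k="0.1">
      <reactant ref="mRNA:ENSG00000000001"/>
    </reaction>
    <reaction id="dec:mRNA:ENSG00000000002" rtype="decay" k="0.1">
      <reactant ref="mRNA:ENSG00000000002"/>
    </reaction>
    <reaction id="dec:mRNA:ENSG00000000003" rtype="decay" k="0.1">
      <reactant ref="mRNA:ENSG00000000003"/>
    </reaction>
    <reaction id="dec:mRNA:ENSG00000000004" rtype="decay" k="0.1">
      <reactant ref="mRNA:ENSG00000000004"/>
    </reaction>
    <reaction id="dec:mRNA:ENSG00000000005" rtype="decay" k="0.1">
      <reactant ref="mRNA:ENSG00000000005"/>
    </reaction>
    <reaction id="dec:pprot:ENSG00000000002" rtype="decay" k="0.05">
      <reactant ref="pprot:ENSG00000000002"/>
    </reaction>
    <reaction id="dec:pprot:ENSG00000000003" rtype="decay" k="0.05">
      <reactant ref="pprot:ENSG00000000003"/>
    </reaction>
    <reaction id="dec:proliferation" rtype="decay" k="0.1">
      <reactant ref="proliferation"/>
    </reaction>
    <reaction id="dec:prot:ENSG00000000001" rtype="decay" k="0.05">
      <reactant ref="prot:ENSG00000000001"/>
    </reaction>
    <reaction id="dec:prot:ENSG00000000002" rtype="decay" k="0.05">
      <reactant ref="prot:ENSG00000000002"/>
    </reaction>
    <reaction id="dec:prot:ENSG00000000003" rtype="decay" k="0.05">
      <reactant ref="prot:ENSG00000000003"/>
    </reaction>
    <reaction id="dec:prot:ENSG00000000004" rtype="decay" k="0.05">
      <reactant ref="prot:ENSG00000000004"/>
    </reaction>
    <reaction id="dec:prot:ENSG00000000005" rtype="decay" k="0.05">
      <reactant ref="prot:ENSG00000000005"/>
    </reaction>
    <reaction id="ph:ENSG00000000002" rtype="phosphorylation" k="0.01" eKd="1e+01">
      <reactant ref="prot:ENSG00000000002"/>
      <product ref="pprot:ENSG00000000002"/>
      <enzyme ref="prot:ENSG00000000001"/>
    </reaction>
    <reaction id="ph:ENSG00000000003" rtype="phosphorylation" k="0.01" eKd="1e+01">
      <reactant ref="prot:ENSG00000000003"/>
      <product ref="pprot:ENSG00000000003"/>
      <enzyme ref="prot:ENSG00000000001"/>
    </reaction>
    <reaction id="tc:ENSG00000000001" rtype="transcription" k="0.01">
      <product ref="mRNA:ENSG00000000001"/>
      <enzyme ref="ENSG00000000001"/>
    </reaction>
    <reaction id="tc:ENSG00000000002" rtype="transcription" k="0.01">
      <product ref="mRNA:ENSG00000000002"/>
      <enzyme ref="ENSG00000000002"/>
    </reaction>
    <reaction id="tc:ENSG00000000003" rtype="transcription" k="0.01">
      <product ref="mRNA:ENSG00000000003"/>
      <enzyme ref="ENSG00000000003"/>
    </reaction>
    <reaction id="tc:ENSG00000000004" rtype="transcription" k="0.01">
      <product ref="mRNA:ENSG00000000004"/>
      <enzyme ref="ENSG00000000004"/>
    </reaction>
    <reaction id="tc:ENSG00000000005" rtype="transcription" k="0.01">
      <product ref="mRNA:ENSG00000000005"/>
      <enzyme ref="ENSG00000000005"/>
    </reaction>
    <reaction id="tl:ENSG00000000001" rtype="translation" k="0.01">
      <product ref="prot:ENSG00000000001"/>
      <enzyme ref="mRNA:ENSG00000000001"/>
    </reaction>
    <reaction id="tl:ENSG00000000002" rtype="translation" k="0.01">
      <product ref="prot:ENSG00000000002"/>
      <enzyme ref="mRNA:ENSG00000000002"/>
    </reaction>
    <reaction id="tl:ENSG00000000003" rtype="translation" k="0.01">
      <product ref="prot:ENSG00000000003"/>
      <enzyme ref="mRNA:ENSG00000000003"/>
    </reaction>
    <reaction id="tl:ENSG00000000004" rtype="translation" k="0.01">
      <product ref="prot:ENSG00000000004"/>
      <enzyme ref="mRNA:ENSG00000000004"/>
    </reaction>
    <reaction id="tl:ENSG00000000005" rtype="translation" k="0.01">
      <product ref="prot:ENSG00000000005"/>
      <enzyme ref="mRNA:ENSG00000000005"/>
    </reaction>
  </listOfReactions>
  <listOfReadouts>
    <readout ref="proliferation"/>
  </listOfReadouts>
</molecularModel>
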