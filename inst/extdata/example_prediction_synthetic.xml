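<?xml version="1.0" encoding="UTF-8"?>
<!-- Worked example of a prediction payload in the BioC subset: one chemical
     annotation in the abstract passage. The passage text is synthetic; the
     annotation's printed location values (offset 103, length 13) are stored
     verbatim from the published worked example even though the surface
     string "hydrocodone" has 11 characters, so this fixture doubles as a
     text-mismatch validation exercise. -->
<collection>
  <source>annobench</source>
  <document>
    <id>CA2073500C</id>
    <passage>
      <infon key="section">T</infon>
      <offset>0</offset>
      <text>Analgesic combination therapy outcomes</text>
    </passage>
    <passage>
      <infon key="section">A</infon>
      <offset>39</offset>
      <text>The opioid component most frequently detected in these samples, hydrocodone, was quantified together with acetaminophen in each formulation.</text>
      <annotation id="1">
        <infon key="type">chemical</infon>
        <infon key="score">0.99</infon>
        <location offset="103" length="13"/>
        <text>hydrocodone</text>
      </annotation>
    </passage>
  </document>
</collection>
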