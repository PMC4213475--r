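<?xml version="1.0"?>
<!-- Small hand-written KGML example exercising gene entries, a group
     (protein complex), a compound intermediary and both edge signs.
     Synthetic: not a KEGG release file. -->
<pathway name="path:toy01" org="toy" title="toy signaling example">
  <entry id="1" name="toy:RCP1" type="gene"/>
  <entry id="2" name="toy:KIN1 toy:KIN2" type="gene"/>
  <entry id="3" name="toy:SCF1" type="gene"/>
  <entry id="4" name="toy:SCF2" type="gene"/>
  <entry id="5" name="undefined" type="group">
    <component id="3"/>
    <component id="4"/>
  </entry>
  <entry id="6" name="cpd:C00165" type="compound"/>
  <entry id="7" name="toy:TF1" type="gene"/>
  <entry id="8" name="toy:INH1" type="gene"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
    <subtype name="phosphorylation" value="+p"/>
  </relation>
  <relation entry1="2" entry2="5" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="5" entry2="6" type="PCrel">
    <subtype name="compound" value="6"/>
  </relation>
  <relation entry1="6" entry2="7" type="PCrel">
    <subtype name="compound" value="6"/>
  </relation>
  <relation entry1="8" entry2="7" type="PPrel">
    <subtype name="inhibition" value="--|"/>
    <subtype name="ubiquitination" value="+u"/>
  </relation>
</pathway>
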