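# ROI hierarchy: 9 major divisions containing 31 subregions, mirroring an
# Allen CCFv3-style merge for ipsilateral mouse-brain connectivity analysis.
# Abbreviations follow standard Allen conventions; the subset shown in the
# source study's figures (MO, ACA, GU, VIS, Str, PTLp, CC, ILA, Mbmot, AUD,
# TEa, CA3, ECT, HPF, CTXsp, VENT, DORpm, MEZ, SSs) is retained verbatim and
# the remaining subregion names are documented placeholders completing the
# 31-region set.
name: mouse_31roi
divisions:
  Isocortex:
    - MO       # somatomotor areas
    - SSp      # primary somatosensory
    - SSs      # supplemental somatosensory
    - GU       # gustatory
    - VIS      # visual areas
    - AUD      # auditory areas
    - ACA      # anterior cingulate
    - ILA      # infralimbic
    - PTLp     # posterior parietal association
    - TEa      # temporal association
    - ECT      # ectorhinal
    - RSP      # retrosplenial (placeholder)
  Olfactory areas:
    - MOB      # main olfactory bulb (placeholder)
    - PIR      # piriform (placeholder)
  Hippocampal formation:
    - HPF      # hippocampal formation (remainder)
    - CA1      # (placeholder)
    - CA3
    - DG       # dentate gyrus (placeholder)
  Cortical subplate:
    - CTXsp
    - CLA      # claustrum (placeholder)
  Cerebral nuclei:
    - Str      # striatum
    - PAL      # pallidum (placeholder)
  Thalamus:
    - VENT     # ventral group
    - DORpm    # polymodal dorsal thalamus
    - DORsm    # sensorimotor dorsal thalamus (placeholder)
  Hypothalamus:
    - MEZ      # medial zone
    - LZ       # lateral zone (placeholder)
  Midbrain:
    - Mbmot    # motor-related midbrain
    - Mbsen    # sensory-related midbrain (placeholder)
  Hindbrain and fiber tracts:
    - P        # pons (placeholder)
    - CC       # corpus callosum
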