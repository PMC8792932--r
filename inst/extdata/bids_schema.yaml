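# Embedded snapshot of the BIDS (1.6) naming rules used for validation:
# entity order, and per datatype the allowed suffixes, allowed entities,
# required entities, and default extension. Imaging-only subset (anat,
# func, fmap, dwi); extend this table to cover further datatypes.
entity_order:
  - task
  - acq
  - ce
  - rec
  - dir
  - run
  - mod
  - echo
  - part
  - recording
datatypes:
  anat:
    suffixes:
      - T1w
      - T2w
      - PDw
      - T2starw
      - FLAIR
      - UNIT1
      - angio
    entities:
      - acq
      - ce
      - rec
      - run
      - part
    required: []
    extension: .nii.gz
  func:
    suffixes:
      - bold
      - sbref
      - cbv
      - phase
    entities:
      - task
      - acq
      - ce
      - rec
      - dir
      - run
      - echo
      - part
    required:
      - task
    extension: .nii.gz
  fmap:
    suffixes:
      - magnitude1
      - magnitude2
      - phasediff
      - phase1
      - phase2
      - magnitude
      - fieldmap
      - epi
    entities:
      - acq
      - ce
      - dir
      - run
    required: []
    extension: .nii.gz
  dwi:
    suffixes:
      - dwi
      - sbref
    entities:
      - acq
      - dir
      - run
      - part
    required: []
    extension: .nii.gz
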