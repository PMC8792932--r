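# Template bidsmap for the built-in "Toy" scan format.
#
# Input dictionary values are regular expressions matched against the
# WHOLE extracted value. Empty patterns impose no constraint. Run-item
# order is the matching precedence: exclude rules come first, the
# extra_data catch-all last.
Options:
  bidscoin:
    version: 0.1.0
    bidsignore: extra_data/
    subprefix: sub-
    sesprefix: ses-
    datatypes:
      - anat
      - func
      - fmap
      - dwi
    unknowntypes:
      - extra_data
    ignoretypes:
      - exclude
  plugins:
    toyscan:
      command: ''
      args: ''
      anon: 'y'
Toy:
  subject: <<filepath:/sub-(.*?)/>>
  session: <<filepath:/ses-(.*?)/>>
  exclude:
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(localizer|scout).*
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        acq: <ProtocolName>
        suffix: <SeriesDescription>
      meta: {}
  anat:
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(mprage|t1w).*
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        acq: <ProtocolName>
        ce: ''
        rec: ''
        run: <<1>>
        part:
          - ''
          - mag
          - phase
          - real
          - imag
          - 1
        suffix: T1w
      meta:
        Comments: <<PatientComments>>
  func:
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(cmrr|bold|fmri|func).*sbref.*
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        task: <ProtocolName>
        acq: <ProtocolName>
        ce: ''
        dir: ''
        rec: ''
        run: <<1>>
        echo: ''
        part:
          - ''
          - mag
          - phase
          - real
          - imag
          - 1
        suffix: sbref
      meta:
        Comments: <<PatientComments>>
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(cmrr|bold|fmri|func).*me[0-9].*
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        task: <ProtocolName>
        acq: <ProtocolName>
        ce: ''
        dir: ''
        rec: ''
        run: <<1>>
        echo: <<EchoNumber>>
        part:
          - ''
          - mag
          - phase
          - real
          - imag
          - 1
        suffix: bold
      meta:
        Comments: <<PatientComments>>
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(cmrr|bold|fmri|func).*
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        task: <ProtocolName>
        acq: <ProtocolName>
        ce: ''
        dir: ''
        rec: ''
        run: <<1>>
        echo: ''
        part:
          - ''
          - mag
          - phase
          - real
          - imag
          - 1
        suffix: bold
      meta:
        Comments: <<PatientComments>>
  fmap:
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(field_?map|b0_?map).*
        SeriesDescription: ''
        ImageTypeText: (?i)m.*
      bids:
        acq: <ProtocolName>
        ce: ''
        dir: ''
        run: <<1>>
        suffix: magnitude1
      meta:
        IntendedFor: <<task>>
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: (?i).*(field_?map|b0_?map).*
        SeriesDescription: ''
        ImageTypeText: (?i)p.*
      bids:
        acq: <ProtocolName>
        ce: ''
        dir: ''
        run: <<1>>
        suffix: phasediff
      meta:
        IntendedFor: <<task>>
  dwi: []
  extra_data:
    - provenance: ''
      properties:
        filepath: ''
        filename: ''
        filesize: ''
        nrfiles: ''
      attributes:
        ProtocolName: ''
        SeriesDescription: ''
        ImageTypeText: ''
      bids:
        acq: <SeriesDescription>
        run: <<1>>
        suffix: <ProtocolName>
      meta: {}
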