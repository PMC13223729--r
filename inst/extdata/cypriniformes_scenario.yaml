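name: cypriniformes_fig
tree: (((zebrafish,rare_minnow)danionidae,(grass_carp,((purse_red_carp,(koi_black,koi_golden)koi)cyprinus,sinocyclocheilus)cyprininae)cyprinidae)cypriniformes,medaka)root;
wgd_branches:
- cyprinus
- sinocyclocheilus
genes_per_segment: 400
loss_rate: 0.0
miscolor_rate: 0.0
seed: 1
events:
  cypriniformes:
  - type: fusion
    chromosomes:
    - T16
    - T17
  - type: fusion
    chromosomes:
    - T18
    - T19
  - type: fission
    chromosome: T01
    breakpoint: 240
  - type: translocation
    donor: T02
    acceptor: T03
    from: 180
    to: 239
  - type: translocation
    donor: T04
    acceptor: T05
    from: 180
    to: 239
  - type: translocation
    donor: T06
    acceptor: T07
    from: 180
    to: 239
  - type: translocation
    donor: T08
    acceptor: T09
    from: 180
    to: 239
  - type: complex
    operations:
    - type: fission
      chromosome: T10
      breakpoint: 240
    - type: fission
      chromosome: T11
      breakpoint: 240
    - type: fusion
      chromosomes:
      - T10.2
      - T11.2
  - type: complex
    operations:
    - type: fission
      chromosome: T12
      breakpoint: 240
    - type: fission
      chromosome: T13
      breakpoint: 240
    - type: fusion
      chromosomes:
      - T12.2
      - T13.2
  grass_carp:
  - type: fusion
    chromosomes:
    - T20
    - T21
  koi:
  - type: fusion
    chromosomes:
    - T22
    - T23
  sinocyclocheilus:
  - type: fusion
    chromosomes:
    - T14
    - T15
  - type: fusion
    chromosomes:
    - T24
    - T20
  - type: fission
    chromosome: T21
    breakpoint: 240
  - type: fission
    chromosome: T22
    breakpoint: 240
outgroup: medaka
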