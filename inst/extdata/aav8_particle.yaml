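# AAV8 particle mass model configuration.
# VP monomer masses are approximate sequence masses for serotype 8
# (VP1 ~736 aa, VP2 ~600 aa, VP3 ~533 aa); they are user inputs, not
# package constants, and should be replaced with construct-specific
# values when available.
vp_monomer_masses_Da:
  VP1: 81600
  VP2: 66600
  VP3: 59800
vp_counts: [5, 5, 50]          # canonical VP1:VP2:VP3 = 5:5:50 60-mer
genome_bases: 2521             # designed full-length ssDNA genome
genome_mass_Da: 780000         # ~0.8 MDa at ~309 Da/nt average
per_base_mass_Da: 330          # generic ssDNA average used for cargo
packaging_capacity_nt: 5200    # wild-type ~4.7 kb plus margin
cargo_candidates:
  - {label: large,    mass_Da: 1600000}   # ~4.8 kb near-capacity genome
  - {label: full,     mass_Da: 800000}    # designed 2,521 nt genome
  - {label: fragment, mass_Da: 200000}    # ~590 nt DNA fragment
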