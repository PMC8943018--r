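# Symmetry-function parameter grids for the four networks.
# Units: lengths in Bohr, Gaussian widths eta in 1/Bohr^2.
# Record order defines the input ordering; g4/eg2 records expand
# to three inputs (local x/y/z axis components).
cutoff_bohr: 12.0
networks:
  net1S:
    - {type: g2, species: O, eta: 0.01, rs: 0.0}
    - {type: g2, species: O, eta: 0.028854, rs: 0.0}
    - {type: g2, species: O, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: O, eta: 0.240225, rs: 0.0}
    - {type: g2, species: O, eta: 0.693145, rs: 0.0}
    - {type: g2, species: O, eta: 2, rs: 0.0}
    - {type: g2, species: H, eta: 0.01, rs: 0.0}
    - {type: g2, species: H, eta: 0.028854, rs: 0.0}
    - {type: g2, species: H, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: H, eta: 0.240225, rs: 0.0}
    - {type: g2, species: H, eta: 0.693145, rs: 0.0}
    - {type: g2, species: H, eta: 2, rs: 0.0}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: -1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: -1}
    - {type: g4, species: all, eta: 0.2, zeta: 1, lambda: 1}
    - {type: g4, species: all, eta: 0.2, zeta: 1, lambda: -1}
    - {type: g4, species: all, eta: 0.2, zeta: 4, lambda: 1}
    - {type: g4, species: all, eta: 0.2, zeta: 4, lambda: -1}
  net1L:
    - {type: eg2, species: O, eta: 0.01, rs: 0.0}
    - {type: eg2, species: O, eta: 0.028854, rs: 0.0}
    - {type: eg2, species: O, eta: 0.0832553, rs: 0.0}
    - {type: eg2, species: O, eta: 0.240225, rs: 0.0}
    - {type: eg2, species: O, eta: 0.693145, rs: 0.0}
    - {type: eg2, species: O, eta: 2, rs: 0.0}
    - {type: eg2, species: H, eta: 0.01, rs: 0.0}
    - {type: eg2, species: H, eta: 0.028854, rs: 0.0}
    - {type: eg2, species: H, eta: 0.0832553, rs: 0.0}
    - {type: eg2, species: H, eta: 0.240225, rs: 0.0}
    - {type: eg2, species: H, eta: 0.693145, rs: 0.0}
    - {type: eg2, species: H, eta: 2, rs: 0.0}
  net2S_O:
    - {type: g2, species: O, eta: 0.01, rs: 0.0}
    - {type: g2, species: O, eta: 0.028854, rs: 0.0}
    - {type: g2, species: O, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: O, eta: 0.240225, rs: 0.0}
    - {type: g2, species: O, eta: 0.693145, rs: 0.0}
    - {type: g2, species: O, eta: 2, rs: 0.0}
    - {type: g2, species: H, eta: 0.01, rs: 0.0}
    - {type: g2, species: H, eta: 0.028854, rs: 0.0}
    - {type: g2, species: H, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: H, eta: 0.240225, rs: 0.0}
    - {type: g2, species: H, eta: 0.693145, rs: 0.0}
    - {type: g2, species: H, eta: 2, rs: 0.0}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: -1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: -1}
    - {type: g4, species: all, eta: 0.2, zeta: 1, lambda: 1}
    - {type: g4, species: all, eta: 0.2, zeta: 4, lambda: 1}
  net2S_H:
    - {type: g2, species: O, eta: 0.01, rs: 0.0}
    - {type: g2, species: O, eta: 0.028854, rs: 0.0}
    - {type: g2, species: O, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: O, eta: 0.240225, rs: 0.0}
    - {type: g2, species: O, eta: 0.693145, rs: 0.0}
    - {type: g2, species: O, eta: 2, rs: 0.0}
    - {type: g2, species: H, eta: 0.01, rs: 0.0}
    - {type: g2, species: H, eta: 0.028854, rs: 0.0}
    - {type: g2, species: H, eta: 0.0832553, rs: 0.0}
    - {type: g2, species: H, eta: 0.240225, rs: 0.0}
    - {type: g2, species: H, eta: 0.693145, rs: 0.0}
    - {type: g2, species: H, eta: 2, rs: 0.0}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 1, lambda: -1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: 1}
    - {type: g4, species: all, eta: 0.01, zeta: 4, lambda: -1}
    - {type: g4, species: all, eta: 0.2, zeta: 1, lambda: 1}
  net2L:
    - {type: eg2, species: O, eta: 0.01, rs: 0.0}
    - {type: eg2, species: O, eta: 0.028854, rs: 0.0}
    - {type: eg2, species: O, eta: 0.0832553, rs: 0.0}
    - {type: eg2, species: O, eta: 0.240225, rs: 0.0}
    - {type: eg2, species: O, eta: 0.693145, rs: 0.0}
    - {type: eg2, species: O, eta: 2, rs: 0.0}
    - {type: eg2, species: H, eta: 0.01, rs: 0.0}
    - {type: eg2, species: H, eta: 0.028854, rs: 0.0}
    - {type: eg2, species: H, eta: 0.0832553, rs: 0.0}
    - {type: eg2, species: H, eta: 0.240225, rs: 0.0}
    - {type: eg2, species: H, eta: 0.693145, rs: 0.0}
    - {type: eg2, species: H, eta: 2, rs: 0.0}
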