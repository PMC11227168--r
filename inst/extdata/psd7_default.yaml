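# psd7_default: seven-protein postsynaptic-density interaction model.
#
# Site topology follows the binding map of the scaffold network: the two
# receptors (NMDAR, AMPAR) each expose two cytoplasmic tails binding the
# tandem PDZ1/2 domains of PSD-95; SynGAP occupies PDZ3; GKAP bridges the
# PSD-95 GK domain to the Shank1 PDZ domain; Shank1 polymerizes head-to-tail
# through its SAM domain and recruits Homer1 via the Homer EVH1 domain;
# Homer1 self-associates through its coiled coil (pairwise chain
# approximation of tetramerization).
#
# Rates: k_on = 1 (arbitrary inverse time per free site pair) for every
# rule; affinities are imposed through k_off alone, so Kd = k_off in copy
# number units. The Kd values below are placeholders at copy-number scale
# (tens to hundreds of molecules per region), chosen once so that the
# receptor/scaffold complexes named in the analysis form at appreciable
# abundance while Shank1/Homer1 grow large polymeric assemblies.
#
# The rule `shank1_pdz_gkap` (Shank1 PDZ : GKAP C-terminus) is the target
# of the hypomorphic mutation scenario (default off-rate factor 5.5).
name: psd7_default
options:
  allow_intra_complex_binding: false
species:
  - name: NMDAR
    sites:
      - {name: ctail, multiplicity: 2}
  - name: AMPAR
    sites:
      - {name: ttail, multiplicity: 2}
  - name: PSD-95
    sites:
      - {name: pdz12, multiplicity: 2}
      - {name: pdz3, multiplicity: 1}
      - {name: gk, multiplicity: 1}
  - name: SynGAP
    sites:
      - {name: pbm, multiplicity: 1}
  - name: GKAP
    sites:
      - {name: gkbd, multiplicity: 1}
      - {name: cterm, multiplicity: 1}
  - name: Shank1
    sites:
      - {name: pdz, multiplicity: 1}
      - {name: ppp, multiplicity: 1}
      - {name: sam_head, multiplicity: 1}
      - {name: sam_tail, multiplicity: 1}
  - name: Homer1
    sites:
      - {name: evh1, multiplicity: 1}
      - {name: cc_a, multiplicity: 1}
      - {name: cc_b, multiplicity: 1}
rules:
  - id: nmdar_psd95
    a: [NMDAR, ctail]
    b: [PSD-95, pdz12]
    k_on: 1.0
    k_off: 50.0
  - id: ampar_psd95
    a: [AMPAR, ttail]
    b: [PSD-95, pdz12]
    k_on: 1.0
    k_off: 50.0
  - id: syngap_psd95
    a: [SynGAP, pbm]
    b: [PSD-95, pdz3]
    k_on: 1.0
    k_off: 20.0
  - id: gkap_psd95
    a: [GKAP, gkbd]
    b: [PSD-95, gk]
    k_on: 1.0
    k_off: 20.0
  - id: shank1_pdz_gkap
    a: [Shank1, pdz]
    b: [GKAP, cterm]
    k_on: 1.0
    k_off: 10.0
  - id: shank1_sam_polymer
    a: [Shank1, sam_head]
    b: [Shank1, sam_tail]
    k_on: 1.0
    k_off: 5.0
  - id: homer_shank1
    a: [Homer1, evh1]
    b: [Shank1, ppp]
    k_on: 1.0
    k_off: 10.0
  - id: homer_cc
    a: [Homer1, cc_a]
    b: [Homer1, cc_b]
    k_on: 1.0
    k_off: 5.0
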