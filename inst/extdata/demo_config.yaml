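# Demonstration run configuration: four synthetic ensembles mirroring the
# binding bookkeeping (mixed system, two dilute references, bulk water),
# all generated in-process at desk scale.
seed: 1
temperature: 298
cutoff: 8
output_dir: eemcc_demo_out
stages:
  reweight: true
  entropy: true
  energy: true
  assemble: true
ensembles:
  bound:
    generate:
      type: solvated_box
      n_protein: 2
      n_polyanion: 5
      n_buffer: 3
      n_water: 60
      n_frames: 100
  dilute_polyanion:
    generate:
      type: solvated_box
      n_protein: 0
      n_polyanion: 5
      n_buffer: 0
      n_water: 40
      n_frames: 80
      box: 24
  dilute_protein:
    generate:
      type: solvated_box
      n_protein: 2
      n_polyanion: 0
      n_buffer: 3
      n_water: 50
      n_frames: 80
  bulk:
    generate:
      type: solvated_box
      n_protein: 0
      n_polyanion: 0
      n_buffer: 0
      n_water: 40
      n_frames: 60
      box: 20
assemble:
  bound: bound
  bulk: bulk
  dilute:
    protein: dilute_protein
    buffer: dilute_protein
    anion: dilute_protein
    polyanion: dilute_polyanion
    cation: dilute_polyanion
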