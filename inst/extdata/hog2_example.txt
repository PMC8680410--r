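# Example scenario: 4 mm implant with 2% HOG beads, 7-day implantation
grid_nx = 100
grid_ny = 100
dx = 0.04            # mm per lattice site
t_end = 7            # days
dt = 0.002           # days; within the diffusion stability bound
bead_type = HOG
bead_fraction = 0.02
seed = 1
n_replicates = 5
output_interval = 0.25
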