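# synthetic drift-rate table (P = 3 participants x C = 2 coherence levels)
# generator: recovery_scenario() packed parameters
# EwL=0.45 Em=0.85 w=1.1 e=0.3 T0=0.3 lam=5 EwR_1=0.38 EwR_2=0.12 alpha_1=3 alpha_2=6 alpha_3=12
# noise_sd=0.01 seed=2026 grid_n=256
participant,coh_8,coh_32
p1,0.0334367155063184,0.132367078466593
p2,0.0241687032639599,0.158809287227469
p3,0.0140006982013465,0.0351106780006265
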