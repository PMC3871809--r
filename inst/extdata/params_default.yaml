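# kiwisim parameter file (units in parameter_registry())
"w_0": 3.2000000000000002  # g; initial fruit water mass
"s_0": 0.5  # g; initial fruit dry matter
"P_f0": 2  # bar; initial fruit turgor
"u_0": 0.01  # g; initial starch mass
"pi_pO": 12.529999999999999  # bar; phloem osmotic pressure from non-sugar solutes
"pi_fO": 6.5  # bar; fruit osmotic pressure from non-sugar solutes
"Y": 2  # bar; turgor yield threshold for plastic growth
"d_1": 15  # DAFB; end of cell-division extensibility plateau
"d_2": 60  # DAFB; end of log-linear extensibility transition
"phi_1": 0.20000000000000001  # bar^-1 h^-1; extensibility during cell division
"phi_2": 0.000135  # bar^-1 h^-1; extensibility at end of transition
"phi_k": 0.028000000000000001  # d^-1; late-season log-extensibility decline rate
"epsilon": 153  # bar; volumetric elastic modulus
"K_m": 0.080000000000000002  # g g^-1; Michaelis constant of active sugar uptake
"nu_1": 0.0050000000000000001  # h^-1; maximal active uptake per g dry matter at 20 C
"Q10_nu": 2  # 1; Q10 of active uptake
"sigma_p": 0.90000000000000002  # 1; phloem membrane reflection coefficient
"sigma_x": 1  # 1; xylem membrane reflection coefficient
"a_x": 0.066000000000000003  # 1; xylem membrane area fraction of fruit surface
"a_p": 0.066000000000000003  # 1; phloem membrane area fraction of fruit surface
"L_x": 0.0071999999999999998  # g cm^-2 bar^-1 h^-1; xylem membrane hydraulic conductivity
"L_p": 0.0071999999999999998  # g cm^-2 bar^-1 h^-1; phloem membrane hydraulic conductivity
"p_s": 0.0030000000000000001  # cm h^-1; membrane solute permeability
"rho_0": 800  # cm h^-1; skin permeance at fit origin
"rho_inf": 25  # cm h^-1; late-season skin permeance asymptote
"k_rho": 0.035000000000000003  # d^-1; skin permeance decline rate
"t_rho": 18  # DAFB; first day of the permeance decline
"L1x": 0.089999999999999997  # g h^-1 bar^-1; pedicel xylem conductance rise amplitude
"L2x": 0.02  # g h^-1 bar^-1; pedicel xylem conductance late plateau
"k1x": 0.10000000000000001  # d^-1; pedicel xylem conductance rise rate
"k2x": 0.035999999999999997  # d^-1; pedicel xylem conductance decline rate
"t_1": 30  # DAFB; pedicel conductance rise midpoint
"t_2": 70  # DAFB; pedicel xylem conductance decline midpoint
"Lp_inf": 0.016  # g h^-1 bar^-1; pedicel phloem conductance asymptote
"k1p": 0.10000000000000001  # d^-1; pedicel phloem conductance rise rate
"A_o": 0.56000000000000005  # 1; structural dry-matter proportion amplitude
"k_o": 0.038399999999999997  # g^-1; decay of structural proportion with dry mass
"s_b": 3.7999999999999998  # %; basal soluble solids percentage
"k_s1": 0.5  # d^-1; maximal starch synthesis rate
"t_r": 165  # DAFB; starch synthesis cutoff time
"t_h": 25  # d; e-folding lead time of synthesis decline
"k_u": 0.055100000000000003  # d^-1; starch breakdown rate
"q_m": 0.000444  # h^-1; maintenance respiration coefficient at 20 C
"q_g": 0.084000000000000005  # 1; growth respiration coefficient
"Q10_r": 1.8999999999999999  # 1; Q10 of maintenance respiration
"R_g": 83.140000000000001  # cm^3 bar mol^-1 K^-1; gas constant
"M_s": 342  # g mol^-1; molar mass of sucrose
"M_w": 18  # g mol^-1; molar mass of water
"H_f": 0.996  # 1; relative humidity of internal air spaces
"rho_sol": 1  # g cm^-3; solution (and fruit) density convention
"gamma": 5.2076000000000002  # cm^2 g^-eta; surface-area allometry coefficient
"eta": 0.64239999999999997  # 1; surface-area allometry exponent
options:
  starch_o_form: proportional
  s_b_base: fresh
  pedicel_sugar_conc: stem
  pedicel_closure: pathway
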