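# Tissue and metal property tables, in the units of the source tables:
# rho kg/m^3, E GPa, nu (-), Ks GPa, theta (-), k m^2, sigma_y MPa.
# "Gingiva" duplicates the Fibrous soft-tissue row (no dedicated gingival
# row is tabulated; the gingiva is modelled as fibrous connective tissue).
tissues:
  - {name: Dentin,         rho: 2100, E: 18.0, nu: 0.27, Ks: 50.0, theta: 0.02, k: 2.0e-16}
  - {name: Cortical,       rho: 1850, E: 14.7, nu: 0.32, Ks: 17.0, theta: 0.04, k: 1.0e-20}
  - {name: Cancellous,     rho: 700,  E: 3.5,  nu: 0.32, Ks: 15.0, theta: 0.7,  k: 3.7e-16}
  - {name: PDL,            rho: 800,  E: 1.0,  nu: 0.30, Ks: 2.3,  theta: 0.8,  k: 1.0e-15}
  - {name: Fibrous,        rho: 800,  E: 0.6,  nu: 0.29, Ks: 2.3,  theta: 0.8,  k: 1.0e-17}
  - {name: Primary matrix, rho: 800,  E: 0.6,  nu: 0.29, Ks: 2.3,  theta: 0.8,  k: 1.0e-17}
  - {name: Granulation,    rho: 800,  E: 0.3,  nu: 0.29, Ks: 2.3,  theta: 0.8,  k: 1.0e-17}
  - {name: Woven bone,     rho: 800,  E: 1.2,  nu: 0.30, Ks: 4.6,  theta: 0.8,  k: 1.0e-16}
  - {name: Gingiva,        rho: 800,  E: 0.6,  nu: 0.29, Ks: 2.3,  theta: 0.8,  k: 1.0e-17}
metals:
  - {name: Ti-6Al-4V, rho: 4500, E: 107.1, nu: 0.31, sigma_y: 800.0}
  - {name: Cu,        rho: 8950, E: 111.4, nu: 0.34, sigma_y: 80.0}
fluid: {Kf: 2.4, rho_f: 1000, eta_f: 1.0e-3}   # Kf GPa, rho_f kg/m^3, eta_f Pa*s
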