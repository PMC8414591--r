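# Template configuration for the musasi command-line interface and
# params_from_config().  Physical quantities may be given either as bare
# numbers (internal units: nm, pN, ms, uM; rate constants 1/s) or as
# {value, unit} mappings; the unit key is documentation of the expected
# unit.  Values below are the package defaults: printed reference values
# where available, calibrated fallbacks otherwise (methods vignette).

model: dse            # dse | bse power-stroke rate law
gamma: 40             # nearest-neighbour cooperativity base
NF: 16                # thin filaments per half-sarcomere
NM: 38                # myosin molecules per filament

SL0:  {value: 1900, unit: nm}     # unloaded sarcomere length
SA0:  {value: 693,  unit: nm^2}   # cross-sectional area per thin filament
RS:   {value: 0.5,  unit: "1"}    # sarcomere volume ratio
dt0:  {value: 0.005, unit: ms}    # baseline Monte Carlo step (5 us)
DT:   {value: 1.25, unit: ms}     # macro (finite-element scale) step

# myosin rod
k_pos: {value: 2, unit: pN/nm}    # rod stiffness, positive strain
k_neg: {value: 1, unit: pN/nm}    # rod stiffness, negative strain
kBT:   {value: 4.28, unit: pN.nm} # thermal energy at 310 K
strain_max: {value: 10, unit: nm} # forced-detachment bound

# free-energy ladder and stroke distances
E0: {value: 0,   unit: pN.nm}
E1: {value: -28, unit: pN.nm}
E2: {value: -50, unit: pN.nm}
s1: {value: 6, unit: nm}
s2: {value: 4, unit: nm}

# attachment / detachment cycle (1/s)
k_np:     {value: 100,  unit: 1/s}
k_pn:     {value: 3000, unit: 1/s}
f_attach: {value: 30,   unit: 1/s}
d_detach: {value: 1500, unit: 1/s}
d_post2:  {value: 75,   unit: 1/s}
k_atp:    {value: 2000, unit: 1/s}

# troponin/tropomyosin unit kinetics
k_ca_on:  {value: 60,  unit: 1/uM/s}
k_ca_off: {value: 150, unit: 1/s}
k_open:   {value: 120, unit: 1/s}
k_close:  {value: 60,  unit: 1/s}

overlap: [0.75, 0.95, 1.05, 1.35]  # filament overlap breakpoints (stretch)

seed: 1
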