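# Built-in cross-linker registry.
# Residual masses follow the vendor fragmentation chemistry:
#   DSSO cleaves at its C-S bonds into an alkene (+C3H2O = 54.010565) and a
#   sulfenic-acid (+C3H4O2S = 103.993200) remnant;
#   DSBU cleaves its central urea into an amide (+C4H7NO = 85.052764) and an
#   isocyanate (+C5H5NO2 = 111.032028) remnant.
# Monolink masses default to intact_mass + 18.010565 (hydrolyzed linker).

[DSS]
name = DSS
specificity_a = K
intact_mass = 138.068080

[BS3]
name = BS3
specificity_a = K
intact_mass = 138.068080

[DSSO]
name = DSSO
specificity_a = K
intact_mass = 158.003765
short_residual = 54.010565
long_residual = 103.993200

[DSBU]
name = DSBU
specificity_a = K
intact_mass = 196.084792
short_residual = 85.052764
long_residual = 111.032028
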