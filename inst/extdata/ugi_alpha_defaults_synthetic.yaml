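# Default upper-GI absorption fractions (alpha_N, dimensionless).
#
# SYNTHETIC RECONSTRUCTION: these values are literature-guided defaults, not
# measured study constants. They follow the standard digestibility picture:
#   - free amino acids / protein: ileal digestibility ~0.90-0.93
#     (true ileal digestibility of mixed dietary protein)
#   - simple sugars: ~0.95-0.98 (near-complete small-intestinal uptake;
#     lactose slightly lower reflecting partial maldigestion)
#   - digestible starch: ~0.90
#   - resistant starch: 0 (escapes small-intestinal amylolysis by definition)
#   - dietary fiber: 0 (no human hydrolases)
#   - fats: ~0.95 (luminal lipolysis/micellar uptake leaves a small residual
#     that reaches the colon, where first-order colonic absorption continues)
# Override any entry with study-specific values via a custom YAML file.
alanine: 0.91
arginine: 0.91
asparagine: 0.91
aspartate: 0.91
glutamate: 0.91
glutamine: 0.91
glycine: 0.91
histidine: 0.91
isoleucine: 0.91
leucine: 0.91
lysine: 0.91
phenylalanine: 0.91
proline: 0.91
serine: 0.91
threonine: 0.91
tryptophan: 0.91
tyrosine: 0.91
valine: 0.91
glucose: 0.98
fructose: 0.95
sucrose: 0.97
lactose: 0.90
starch: 0.90
resistant_starch: 0.0
fiber: 0.0
fat_saturated: 0.95
fat_unsaturated: 0.95
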