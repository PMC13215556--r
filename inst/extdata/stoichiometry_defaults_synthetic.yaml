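# Fermentation product-ratio defaults (catabolic COD split per substrate).
#
# SYNTHETIC RECONSTRUCTION: plausible mixed-culture fermentation spectra,
# shipped as editable configuration. Carbohydrate fermentation is limited to
# the three main SCFAs (no H2 by default); amino-acid fermentation includes
# an H2 fraction that feeds methanogenesis. Each split is the fraction of
# catabolic COD routed to the product and sums to 1; the builder then scales
# by (1 - fs) and adds the fs biomass term.
#
# fs: fraction of donor electrons to cell synthesis for fermenters.
# fs_m: same for hydrogenotrophic methanogens (low anaerobic-autotroph yield).
fs: 0.2
fs_m: 0.08

# one split for all carbohydrate substrates (sugars, starch, fiber)
carbohydrate:
  acetate: 0.60
  propionate: 0.25
  butyrate: 0.15

# optional 4-product split used only when carbohydrate H2 production is
# switched on for sensitivity analysis (carb_h2 = TRUE)
carbohydrate_h2:
  acetate: 0.55
  propionate: 0.22
  butyrate: 0.13
  h2: 0.10

# per-amino-acid splits (Stickland-style variation across donors/acceptors)
amino_acids:
  alanine:       {acetate: 0.55, propionate: 0.15, butyrate: 0.05, h2: 0.25}
  arginine:      {acetate: 0.50, propionate: 0.20, butyrate: 0.10, h2: 0.20}
  asparagine:    {acetate: 0.60, propionate: 0.15, butyrate: 0.05, h2: 0.20}
  aspartate:     {acetate: 0.60, propionate: 0.15, butyrate: 0.05, h2: 0.20}
  glutamate:     {acetate: 0.55, propionate: 0.05, butyrate: 0.25, h2: 0.15}
  glutamine:     {acetate: 0.55, propionate: 0.05, butyrate: 0.25, h2: 0.15}
  glycine:       {acetate: 0.75, propionate: 0.05, butyrate: 0.05, h2: 0.15}
  histidine:     {acetate: 0.50, propionate: 0.15, butyrate: 0.20, h2: 0.15}
  isoleucine:    {acetate: 0.35, propionate: 0.30, butyrate: 0.15, h2: 0.20}
  leucine:       {acetate: 0.35, propionate: 0.15, butyrate: 0.30, h2: 0.20}
  lysine:        {acetate: 0.45, propionate: 0.05, butyrate: 0.35, h2: 0.15}
  phenylalanine: {acetate: 0.45, propionate: 0.25, butyrate: 0.15, h2: 0.15}
  proline:       {acetate: 0.40, propionate: 0.30, butyrate: 0.15, h2: 0.15}
  serine:        {acetate: 0.60, propionate: 0.15, butyrate: 0.05, h2: 0.20}
  threonine:     {acetate: 0.50, propionate: 0.25, butyrate: 0.05, h2: 0.20}
  tryptophan:    {acetate: 0.45, propionate: 0.25, butyrate: 0.15, h2: 0.15}
  tyrosine:      {acetate: 0.45, propionate: 0.25, butyrate: 0.15, h2: 0.15}
  valine:        {acetate: 0.35, propionate: 0.35, butyrate: 0.10, h2: 0.20}
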