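# Generates inst/extdata/fingerprint_schema.tsv, the bundled fingerprint
# bit definitions. Five families: MACCS and FP3 delegated to OpenBabel's
# built-in pattern sets (generator tags), plus curated SMARTS sets for
# general functional-group keys ("substructure"), count/ring/atom-pair
# keys in the style of the PubChem CACTVS sections ("pubchem_like"), and
# ring-system / pharmacophore motifs ("klekota_roth").
# Every SMARTS is validated by matching it against a probe molecule set
# with OpenBabel before it is written; an invalid pattern aborts.
suppressMessages(library(ChemmineOB))

bits <- list()
add <- function(family, name, definition, min_count = 1L) {
  bits[[length(bits) + 1L]] <<- data.frame(
    bit_id = paste0(family, ":", name), family = family,
    definition = definition, min_count = as.integer(min_count),
    stringsAsFactors = FALSE)
}

## ---- OpenBabel generator families -------------------------------------
for (k in 1:166) add("maccs", sprintf("%03d", k), sprintf("openbabel:MACCS:%d", k))
for (k in 1:55)  add("fp3",   sprintf("%02d", k), sprintf("openbabel:FP3:%d", k))

## ---- substructure: general functional-group keys ----------------------
fg <- c(
  alkene                = "[CX3]=[CX3]",
  alkyne                = "[CX2]#[CX2]",
  allene                = "[CX3]=[CX2]=[CX3]",
  arene                 = "c1ccccc1",
  fused_arene           = "c1ccc2ccccc2c1",
  heteroarene           = "[a;!c]",
  alcohol               = "[#6][OX2H]",
  primary_alcohol       = "[CX4H2][OX2H]",
  secondary_alcohol     = "[CX4H1][OX2H]",
  tertiary_alcohol      = "[CX4]([#6])([#6])([#6])[OX2H]",
  phenol                = "c[OX2H]",
  enol                  = "[CX3]=[CX3][OX2H]",
  ether                 = "[OD2]([#6])[#6]",
  dialkyl_ether         = "[CX4][OX2][CX4]",
  aryl_ether            = "c[OX2][#6]",
  epoxide               = "C1OC1",
  peroxide              = "[OX2][OX2]",
  aldehyde              = "[CX3H1](=O)[#6]",
  ketone                = "[#6][CX3](=O)[#6]",
  carboxylic_acid       = "[CX3](=O)[OX2H1]",
  carboxylate           = "[CX3](=O)[O-]",
  ester                 = "[#6][CX3](=O)[OX2H0][#6]",
  lactone               = "[C;R](=O)[O;R]",
  carbonate             = "[OX2][CX3](=[OX1])[OX2]",
  anhydride             = "[CX3](=O)[OX2][CX3](=O)",
  amide                 = "[NX3][CX3](=[OX1])",
  primary_amide         = "[NX3H2][CX3](=[OX1])",
  secondary_amide       = "[NX3H1]([#6])[CX3](=[OX1])",
  tertiary_amide        = "[NX3]([#6])([#6])[CX3](=[OX1])",
  lactam                = "[N;R][C;R](=O)",
  carbamate             = "[NX3][CX3](=[OX1])[OX2]",
  urea                  = "[NX3][CX3](=[OX1])[NX3]",
  thiourea              = "[NX3][CX3](=[SX1])[NX3]",
  guanidine             = "[NX3][CX3](=[NX2])[NX3]",
  amidine               = "[CX3](=[NX2])[NX3]",
  primary_amine         = "[NX3;H2;!$(NC=O);!$(N=*)][#6]",
  secondary_amine       = "[NX3;H1;!$(NC=O);!$(N=*)]([#6])[#6]",
  tertiary_amine        = "[NX3;H0;!$(NC=O);!$(N=*);!$([N+])]([#6])([#6])[#6]",
  aryl_amine            = "c[NX3]",
  quaternary_ammonium   = "[NX4+]",
  hydroxylamine         = "[NX3][OX2H]",
  hydrazine             = "[NX3][NX3]",
  hydrazone             = "[NX3][NX2]=[CX3]",
  imine                 = "[CX3]=[NX2]",
  oxime                 = "[CX3]=[NX2][OX2H]",
  nitrile               = "[CX2]#[NX1]",
  isocyanate            = "[NX2]=[CX2]=[OX1]",
  isothiocyanate        = "[NX2]=[CX2]=[SX1]",
  nitro                 = "[NX3](=O)=O",
  nitro_charged         = "[NX3+](=O)[O-]",
  nitroso               = "[NX2]=[OX1]",
  azide                 = "[NX2]=[NX2+]=[NX1-]",
  azo                   = "[#6][NX2]=[NX2][#6]",
  diazonium             = "[NX2+]#[NX1]",
  nitrate_ester         = "[OX2][NX3](=O)=O",
  thiol                 = "[#6][SX2H]",
  thioether             = "[SD2]([#6])[#6]",
  disulfide             = "[SX2][SX2]",
  thiocarbonyl          = "[CX3]=[SX1]",
  thioester             = "[SX2][CX3](=[OX1])",
  sulfoxide             = "[SX3](=[OX1])([#6])[#6]",
  sulfone               = "[SX4](=[OX1])(=[OX1])([#6])[#6]",
  sulfonic_acid         = "[SX4](=[OX1])(=[OX1])[OX2H]",
  sulfonate_ester       = "[SX4](=[OX1])(=[OX1])[OX2][#6]",
  sulfonamide           = "[SX4](=[OX1])(=[OX1])[NX3]",
  sulfamate             = "[NX3][SX4](=[OX1])(=[OX1])[OX2]",
  sulfate_ester         = "[OX2][SX4](=[OX1])(=[OX1])[OX2]",
  phosphine             = "[PX3]",
  phosphine_oxide       = "[PX4](=[OX1])([#6])([#6])[#6]",
  phosphonate           = "[PX4](=[OX1])([OX2])[#6]",
  phosphate_ester       = "[OX2][PX4](=[OX1])([OX2])[OX2]",
  phosphoramide         = "[NX3][PX4](=[OX1])",
  fluoro                = "[#6]F",
  chloro                = "[#6]Cl",
  bromo                 = "[#6]Br",
  iodo                  = "[#6]I",
  trifluoromethyl       = "[CX4](F)(F)F",
  trichloromethyl       = "[CX4](Cl)(Cl)Cl",
  aryl_halide           = "c[F,Cl,Br,I]",
  alkyl_halide          = "[CX4][F,Cl,Br,I]",
  acyl_halide           = "[CX3](=[OX1])[F,Cl,Br,I]",
  vinyl_halide          = "[CX3]=[CX3][F,Cl,Br,I]",
  gem_dihalide          = "[CX4]([F,Cl,Br,I])[F,Cl,Br,I]",
  methyl                = "[CX4H3]",
  methylene_chain       = "[CX4H2]",
  methine               = "[CX4H1]",
  quaternary_carbon     = "[CX4]([#6])([#6])([#6])[#6]",
  isopropyl             = "[CX4H1]([CX4H3])[CX4H3]",
  tert_butyl            = "[CX4]([CX4H3])([CX4H3])[CX4H3]",
  long_chain            = "[CX4H2][CX4H2][CX4H2][CX4H2]",
  benzyl                = "c[CX4H2]",
  styryl                = "c[CX3]=[CX3]",
  benzoyl               = "c[CX3]=[OX1]",
  acetyl                = "[CX4H3][CX3]=[OX1]",
  formyl                = "[CX3H1]=[OX1]",
  carboxybenzene        = "c[CX3](=O)[OX2H1]",
  anisole               = "c[OX2][CX4H3]",
  toluene_methyl        = "c[CX4H3]",
  aniline_nh2           = "c[NX3H2]",
  benzamide             = "c[CX3](=[OX1])[NX3]",
  nitrobenzene          = "c[NX3](=O)=O",
  benzonitrile          = "c[CX2]#[NX1]",
  halopyridine          = "n1ccccc1",
  alpha_halo_ketone     = "[CX3](=O)[CX4][F,Cl,Br,I]",
  michael_acceptor      = "[CX3]=[CX3][CX3]=[OX1]",
  enamine               = "[NX3][CX3]=[CX3]",
  enol_ether            = "[OX2][CX3]=[CX3]",
  acetal                = "[CX4]([OX2])([OX2])",
  hemiacetal            = "[CX4]([OX2H])[OX2][#6]",
  carbamic_acid         = "[NX3][CX3](=[OX1])[OX2H]",
  imide                 = "[CX3](=[OX1])[NX3][CX3](=[OX1])",
  n_oxide               = "[NX4+][O-]",
  aromatic_n_oxide      = "[n+][O-]",
  betaine_carboxylate   = "[NX4+][CX4][CX3](=[OX1])[O-]",
  zwitterion_n          = "[NX4+,NX3+]",
  anionic_o             = "[O-]",
  alpha_amino_acid      = "[NX3][CX4][CX3](=[OX1])[OX2H,OX1-]",
  glycol                = "[OX2H][CX4][CX4][OX2H]",
  vicinal_diamine       = "[NX3][CX4][CX4][NX3]",
  amino_alcohol         = "[NX3][CX4][CX4][OX2H]",
  haloacetamide         = "[NX3][CX3](=[OX1])[CX4][F,Cl,Br,I]",
  aryl_sulfonamide      = "c[SX4](=[OX1])(=[OX1])[NX3]",
  aryl_carbamate        = "c[OX2][CX3](=[OX1])[NX3]",
  aryl_urea             = "c[NX3][CX3](=[OX1])[NX3]",
  thiophosphate         = "[PX4](=[SX1])",
  organosilicon         = "[Si]",
  boronic               = "[BX3]",
  carbodiimide          = "[NX2]=[CX2]=[NX2]"
)
for (i in seq_along(fg)) add("substructure", names(fg)[i], fg[[i]])

## ---- pubchem_like: element counts, ring keys, bonded atom pairs -------
count_smarts <- function(pattern, n) paste(rep(pattern, n), collapse = ".")
elem_counts <- list(
  C  = c(2, 4, 8, 16, 24, 32), c_arom = c(6, 10, 14),
  N  = c(1, 2, 4, 6), O = c(1, 2, 4, 8, 12), S = c(1, 2, 4),
  P  = c(1, 2), F = c(1, 2, 4, 8), Cl = c(1, 2, 4), Br = c(1, 2),
  I  = c(1, 2), Si = 1, B = 1
)
atom_pat <- c(C = "[#6]", c_arom = "c", N = "[#7]", O = "[#8]", S = "[#16]",
              P = "[#15]", F = "[F]", Cl = "[Cl]", Br = "[Br]", I = "[I]",
              Si = "[Si]", B = "[#5]")
for (el in names(elem_counts)) {
  for (n in elem_counts[[el]]) {
    add("pubchem_like", sprintf("count_%s_ge%d", el, n), atom_pat[[el]], n)
  }
}
ring_keys <- list(
  ring3 = "[R]1[R][R]1", ring4 = "[R]1[R][R][R]1",
  ring5 = "[R]1[R][R][R][R]1", ring6 = "[R]1[R][R][R][R][R]1",
  ring7 = "[R]1[R][R][R][R][R][R]1", ring8 = "[R]1[R][R][R][R][R][R][R]1",
  sat_carbocycle5 = "C1CCCC1", sat_carbocycle6 = "C1CCCCC1",
  arom5 = "[a]1[a][a][a][a]1", arom6 = "[a]1[a][a][a][a][a]1",
  n_heterocycle = "[#7;R]", o_heterocycle = "[#8;R]", s_heterocycle = "[#16;R]",
  ring_atom = "[R]", fused_ring_atom = "[R2]", spiro_or_bridge = "[R3]"
)
for (nm in names(ring_keys)) add("pubchem_like", nm, ring_keys[[nm]])
add("pubchem_like", "benzene_ge2", "c1ccccc1", 2)
add("pubchem_like", "benzene_ge3", "c1ccccc1", 3)
add("pubchem_like", "ring6_ge2", "[R]1[R][R][R][R][R]1", 2)
add("pubchem_like", "ring6_ge3", "[R]1[R][R][R][R][R]1", 3)
add("pubchem_like", "ring_atom_ge8", "[R]", 8)
add("pubchem_like", "ring_atom_ge12", "[R]", 12)
pairs <- c(
  "C-C" = "[#6;!a]-[#6;!a]", "C=C" = "[#6]=[#6]", "C#C" = "[#6]#[#6]",
  "c:c" = "c:c", "C-N" = "[#6]-[#7]", "C=N" = "[#6]=[#7]", "C#N" = "[#6]#[#7]",
  "c:n" = "c:n", "C-O" = "[#6]-[#8]", "C=O" = "[#6]=[#8]", "c-O" = "c-[#8]",
  "C-S" = "[#6]-[#16]", "C=S" = "[#6]=[#16]", "c:s" = "c:s", "c:o" = "c:o",
  "C-P" = "[#6]-[#15]", "N-N" = "[#7]-[#7]", "N=N" = "[#7]=[#7]",
  "n:n" = "n:n", "N-O" = "[#7]-[#8]", "N=O" = "[#7]=[#8]",
  "O-P" = "[#8]-[#15]", "P=O" = "[#15]=[#8]", "O-S" = "[#8]-[#16]",
  "S=O" = "[#16]=[#8]", "S-S" = "[#16]-[#16]", "N-P" = "[#7]-[#15]",
  "P=S" = "[#15]=[#16]", "C-F" = "[#6]-[F]", "C-Cl" = "[#6]-[Cl]",
  "C-Br" = "[#6]-[Br]", "C-I" = "[#6]-[I]", "N-S" = "[#7]-[#16]"
)
for (i in seq_along(pairs)) {
  nm <- chartr("-=#:", "sdta", names(pairs)[i])   # single/double/triple/aromatic
  add("pubchem_like", paste0("bond_", nm), pairs[[i]])
}

## ---- klekota_roth: ring systems and pharmacophore-style motifs --------
kr <- c(
  pyridine            = "c1ccncc1",
  pyrimidine          = "c1cncnc1",
  pyrazine            = "c1cnccn1",
  pyridazine          = "c1ccnnc1",
  triazine            = "c1ncncn1",
  pyrrole             = "c1cc[nH]c1",
  n_subst_pyrrole     = "c1ccn(c1)[#6]",
  furan               = "c1ccoc1",
  thiophene           = "c1ccsc1",
  imidazole           = "c1cnc[nH]1",
  n_imidazole         = "c1cncn1",
  pyrazole            = "c1cn[nH]c1",
  oxazole             = "c1ocnc1",
  isoxazole           = "c1oncc1",
  thiazole            = "c1scnc1",
  isothiazole         = "c1sncc1",
  triazole_123        = "c1nn[nH]c1",
  triazole_134        = "c1nc[nH]n1",
  tetrazole           = "c1nnn[nH]1",
  oxadiazole          = "c1nnco1",
  thiadiazole         = "c1nncs1",
  naphthalene         = "c1ccc2ccccc2c1",
  quinoline           = "c1ccc2ncccc2c1",
  isoquinoline        = "c1ccc2cnccc2c1",
  quinazoline         = "c1ccc2ncncc2c1",
  quinoxaline         = "c1ccc2nccnc2c1",
  indole              = "c1ccc2[nH]ccc2c1",
  benzimidazole       = "c1ccc2[nH]cnc2c1",
  benzoxazole         = "c1ccc2ocnc2c1",
  benzothiazole       = "c1ccc2scnc2c1",
  benzofuran          = "c1ccc2occc2c1",
  benzothiophene      = "c1ccc2sccc2c1",
  indazole            = "c1ccc2[nH]ncc2c1",
  benzotriazole       = "c1ccc2[nH]nnc2c1",
  purine              = "c1ncc2[nH]cnc2n1",
  pteridine           = "c1ncc2nccnc2n1",
  carbazole           = "c1ccc2c(c1)[nH]c1ccccc12",
  dibenzofuran        = "c1ccc2c(c1)oc1ccccc12",
  acridine            = "c1ccc2nc3ccccc3cc2c1",
  anthracene          = "c1ccc2cc3ccccc3cc2c1",
  phenanthrene_like   = "c1ccc2ccc3ccccc3c2c1",
  biphenyl            = "c1ccccc1-c1ccccc1",
  diphenylmethane     = "c1ccccc1[CX4H2]c1ccccc1",
  diphenyl_ether      = "c1ccccc1[OX2]c1ccccc1",
  diphenylamine       = "c1ccccc1[NX3]c1ccccc1",
  benzophenone        = "c1ccccc1C(=O)c1ccccc1",
  stilbene            = "c1ccccc1C=Cc1ccccc1",
  azobenzene          = "c1ccccc1N=Nc1ccccc1",
  pyrrolidine         = "C1CCNC1",
  piperidine          = "C1CCNCC1",
  piperazine          = "C1CNCCN1",
  morpholine          = "C1COCCN1",
  thiomorpholine      = "C1CSCCN1",
  azetidine           = "C1CNC1",
  aziridine           = "C1CN1",
  tetrahydrofuran     = "C1CCOC1",
  tetrahydropyran     = "C1CCOCC1",
  dioxolane           = "C1OCCO1",
  dioxane             = "C1COCCO1",
  n_methylpiperazine  = "CN1CCNCC1",
  indoline            = "C1Cc2ccccc2N1",
  tetrahydroquinoline = "C1Cc2ccccc2NC1",
  benzodioxole        = "C1Oc2ccccc2O1",
  chromene            = "c1ccc2c(c1)CCO2",
  coumarin            = "O=c1ccc2ccccc2o1",
  chromone            = "O=c1ccoc2ccccc12",
  flavone_core        = "O=c1cc(-c2ccccc2)oc2ccccc12",
  quinolone           = "O=c1cc[nH]c2ccccc12",
  uracil              = "O=c1cc[nH]c(=O)[nH]1",
  hydantoin           = "O=C1NC(=O)CN1",
  barbiturate         = "O=C1NC(=O)NC(=O)C1",
  succinimide         = "O=C1CCC(=O)N1",
  maleimide           = "O=C1C=CC(=O)N1",
  phthalimide         = "O=C1c2ccccc2C(=O)N1",
  oxazolidinone       = "O=C1OCCN1",
  pyridone            = "O=c1cccc[nH]1",
  n_methylpyrrolidone = "CN1CCCC1=O",
  beta_lactam         = "O=C1CCN1",
  steroid_decalin     = "C1CCC2CCCCC2C1",
  cyclopropyl         = "C1CC1",
  cyclobutyl          = "C1CCC1",
  cycloheptane        = "C1CCCCCC1",
  adamantane_cage     = "C1C2CC3CC1CC(C2)C3",
  aryl_piperazine     = "c1ccccc1N1CCNCC1",
  benzyl_amine        = "c1ccccc1[CX4H2][NX3]",
  phenethylamine      = "c1ccccc1[CX4H2][CX4H2][NX3]",
  aryloxy_acetic      = "c[OX2][CX4H2][CX3](=[OX1])",
  salicyl             = "c1ccc(c(c1)[CX3]=[OX1])[OX2H]",
  catechol            = "c1cc(c(cc1)[OX2H])[OX2H]",
  methylenedioxyphenyl= "c1cc2c(cc1)OCO2",
  methoxyphenol       = "c1cc([OX2H])c([OX2][CX4H3])cc1",
  guanidinium_arg     = "[NX3][CX3](=[NX2+,NX2])[NX3]",
  imidazoline         = "C1CN=CN1",
  sulfanilamide       = "c1cc([NX3H2])ccc1[SX4](=[OX1])(=[OX1])[NX3]",
  dichlorophenyl      = "c1cc(Cl)cc(Cl)c1",
  para_halophenol     = "c1cc([OX2H])ccc1[F,Cl,Br,I]",
  aminopyridine       = "c1ccnc(c1)[NX3H2]",
  halopyrimidine      = "c1cnc(nc1)[F,Cl,Br,I]",
  trifluoromethylaryl = "c[CX4](F)(F)F",
  nitrophenol         = "c1cc([OX2H])ccc1[NX3](=O)=O",
  aryl_ketone_amine   = "c1ccccc1[CX3](=[OX1])[CX4][NX3]",
  triphenyl           = "c1ccccc1-c1ccccc1-c1ccccc1"
)
for (i in seq_along(kr)) add("klekota_roth", names(kr)[i], kr[[i]])

schema <- do.call(rbind, bits)
stopifnot(!anyDuplicated(schema$bit_id))

## ---- validate every SMARTS against a probe set ------------------------
probes <- c("c1ccccc1CC(=O)NC1CCNCC1", "CC(=O)Oc1ccccc1C(=O)O",
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]",
            "C[Si](C)(C)C", "OB(O)c1ccccc1", "C1C2CC3CC1CC(C2)C3",
            "FC(F)(F)c1ccc2nc(N3CCNCC3)ccc2c1", "CCCCCCCCCCCC(=O)OCC(O)CO")
mols <- forEachMol("SMILES", paste(probes, collapse = "\n"), identity)
is_smarts <- !grepl("^openbabel:", schema$definition)
for (i in which(is_smarts)) {
  r <- tryCatch(smartsSearch_OB(mols, schema$definition[i]),
                error = function(e) NULL)
  if (is.null(r) || length(r) != length(probes)) {
    stop("invalid SMARTS for bit ", schema$bit_id[i], ": ", schema$definition[i])
  }
}
cat("validated", sum(is_smarts), "SMARTS bits;",
    sum(!is_smarts), "generator bits; total", nrow(schema), "\n")
write.table(schema, "inst/extdata/fingerprint_schema.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote inst/extdata/fingerprint_schema.tsv\n")
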