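# Shared fixtures built in code.

# Table 2 "Compounds in Method" (per class; the printed CER row is the
# six-class ceramide family total, expanded here as 35 per member class).
table2_counts <- function() {
  c(CAR = 48, CER = 35, dhCER = 35, glcCER = 35, `glc-dhCER` = 35,
    lacCER = 35, `lac-dhCER` = 35,
    DG = 630, DGDG = 630, FA = 35, LPA = 35, LPC = 35, LPE = 35,
    LPG = 35, LPI = 35, LPS = 35, MG = 35, MGDG = 630, PA = 630,
    PC = 630, PE = 630, PG = 630, PI = 630, PS = 630, SM = 35, TG = 1834)
}

# Kendrick grid fixture: theoretical FA-chain m/z on a (C, DB) grid with a
# retention-time rule that satisfies the expected grid ordering
# (RT grows with carbons, shrinks with double bonds).
kendrick_grid <- function(class = "FA", carbons = seq(14, 22, 2), dbs = 0:3,
                          rt_base = 2, rt_c = 0.4, rt_db = 0.3) {
  g <- expand.grid(total_carbons = carbons, total_db = dbs)
  sp <- lapply(seq_len(nrow(g)), function(i)
    species("FA", chain_label(g$total_carbons[i], g$total_db[i])))
  mz <- vapply(sp, precursor_mz, 0)
  tibble::tibble(
    transition_id = paste0(class, " ", g$total_carbons, ":", g$total_db),
    mz = mz,
    rt = rt_base + rt_c * (g$total_carbons - min(carbons)) / 2 -
      rt_db * g$total_db,
    class = class,
    total_carbons = g$total_carbons,
    total_db = g$total_db)
}

# brute-force multiset enumeration oracle: sorted k-tuples over n items
brute_force_multisets <- function(n, k) {
  idx <- switch(as.character(k),
    "1" = matrix(seq_len(n), ncol = 1),
    "2" = {
      g <- expand.grid(i = seq_len(n), j = seq_len(n))
      unique(t(apply(as.matrix(g), 1, sort)))
    },
    "3" = {
      g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
      unique(t(apply(as.matrix(g), 1, sort)))
    })
  nrow(idx)
}

# small maturation study used by several analysis tests
small_study <- function(seed = 11, noise_cv = 0.10, missing_rate = 0.05,
                        n_per_class = 6) {
  design <- maturation_design(noise_cv = noise_cv,
                              missing_rate = missing_rate)
  compounds <- default_study_compounds(n_per_class = n_per_class)
  sim <- simulate_maturation(design, compounds, seed = seed)
  conc <- semi_quantify(sim$areas, sim$samples,
                        compounds = compounds)
  conc <- impute_missing(conc, seed = seed)
  list(sim = sim, conc = conc,
       am = analysis_matrix(conc, sim$samples))
}

trend_truth <- function() {
  c(LPC = 1, LPE = 1, PE = 1, PG = 1, PI = 1,
    CER = -1, MG = -1, LPG = -1, DGDG = -1, MGDG = -1)
}

# Frozen reference panel: hand-derived molecular formulas, one species per
# class, with monoisotopic masses computed once via an independent
# atomic-mass route and frozen here as release-gate constants.
reference_panel <- function() {
  m <- matrix(c(
    "CAR", "16:0", "C23H45NO4", "399.33486",
    "CER", "d18:1/16:0", "C34H67NO3", "537.51210",
    "dhCER", "d18:0/16:0", "C34H69NO3", "539.52775",
    "glcCER", "d18:1/18:0", "C42H81NO8", "727.59622",
    "glc-dhCER", "d18:0/16:0", "C40H79NO8", "701.58057",
    "lacCER", "d18:1/16:0", "C46H87NO13", "861.61774",
    "lac-dhCER", "d18:0/16:0", "C46H89NO13", "863.63339",
    "DG", "16:0_18:1", "C37H70O5", "594.52233",
    "TG", "16:0_18:1_18:1", "C55H102O6", "858.76764",
    "MG", "18:1", "C21H40O4", "356.29266",
    "MGDG", "16:0_18:0", "C43H82O10", "758.59080",
    "DGDG", "18:0_18:0", "C51H96O15", "948.67492",
    "FA", "16:0", "C16H32O2", "256.24023",
    "LPA", "16:0", "C19H39O7P", "410.24334",
    "LPC", "16:0", "C24H50NO7P", "495.33249",
    "LPE", "18:1", "C23H46NO7P", "479.30119",
    "LPG", "16:0", "C22H45O9P", "484.28012",
    "LPI", "18:0", "C27H53O12P", "600.32746",
    "LPS", "16:0", "C22H44NO9P", "497.27537",
    "PA", "16:0_18:1", "C37H71O8P", "674.48866",
    "PC", "16:0_18:1", "C42H82NO8P", "759.57781",
    "PE", "16:0_18:1", "C39H76NO8P", "717.53086",
    "PG", "16:0_18:1", "C40H77O10P", "748.52544",
    "PI", "16:0_18:1", "C43H81O13P", "836.54148",
    "PS", "16:0_18:1", "C40H76NO10P", "761.52068",
    "SM", "d18:1/16:0", "C39H79N2O6P", "702.56757"),
    ncol = 4, byrow = TRUE)
  tibble::tibble(class = m[, 1], chains = m[, 2], formula = m[, 3],
                 ref_mass = as.numeric(m[, 4]))
}

strip_base <- function(chains) sub("^d18:[01]/", "", chains)
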