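test_that("per-class transition counts reproduce the published method sizes", {
  expect_equal(nrow(build_class_transitions("PE")), 630)
  expect_equal(nrow(build_class_transitions("SM")), 35)
  expect_equal(nrow(build_class_transitions("FA")), 35)
  fam <- c("CER", "dhCER", "glcCER", "glc-dhCER", "lacCER", "lac-dhCER")
  expect_equal(sum(vapply(fam, function(cl)
    nrow(build_class_transitions(cl)), 0)), 210)
})

test_that("SM transitions all monitor the phosphocholine head", {
  sm <- build_class_transitions("SM")
  expect_true(all(sm$q2 == 184.1))
  expect_true(all(sm$polarity == "pos"))
})

test_that("FA transitions monitor the intact deprotonated ion", {
  fa <- build_class_transitions("FA")
  expect_equal(fa$q1, fa$q2)
})

test_that("audit mode emits one candidate per distinct chain of the multiset", {
  pe <- build_class_transitions("PE", leaving = "all")
  # 595 two-distinct-chain species contribute 2, 35 homo-pairs contribute 1
  expect_equal(nrow(pe), 595 * 2 + 35)
})

test_that("dedup merges exact-mass collisions and is idempotent", {
  tg <- build_class_transitions("TG")
  dd <- dedup_transitions(tg)
  expect_equal(nrow(dd), 1981)
  expect_equal(dedup_transitions(dd), dd)
  expect_equal(nrow(dedup_transitions(tg[0, ])), 0)

  # brute-force oracle: distinct rounded (Q1, Q2) pairs of the raw list
  key <- unique(paste(sprintf("%.1f", tg$q1), sprintf("%.1f", tg$q2)))
  expect_equal(nrow(dd), length(key))

  # two species sharing total composition and leaving chain merge into one
  merged <- dd[dd$n_species > 1, ][1, ]
  ids <- strsplit(merged$species, ";")[[1]]
  expect_gte(length(ids), 2)
})

test_that("every deduplicated transition is reproducible from a species id", {
  dd <- dedup_transitions(build_class_transitions("TG"))
  set.seed(1)
  for (i in sample(nrow(dd), 25)) {
    sp <- species("TG", sub("^TG ", "", dd$transition_id[i]))
    expect_equal(precursor_mz(sp), dd$q1[i], tolerance = 1e-9)
    expect_equal(product_mz(sp), dd$q2[i], tolerance = 1e-9)
  }
})

test_that("full method build matches the published per-class counts", {
  m <- build_method()
  counts <- stats::setNames(m$summary$compounds_in_method, m$summary$class)
  printed <- table2_counts()
  agree <- setdiff(names(printed), c("CAR", "TG"))
  expect_equal(counts[agree], printed[agree])
  # documented known differences: these must not silently change
  expect_equal(unname(counts["CAR"]), 35)  # printed 48, producing space unstated
  expect_equal(unname(counts["TG"]), 1981) # printed 1834, rule unstated
})

test_that("method splits by polarity into a clean partition with 21 IS", {
  m <- build_method()
  all_tr <- method_transitions(m)
  expect_equal(nrow(m$positive) + nrow(m$negative), nrow(all_tr))
  expect_true(all(m$positive$polarity == "pos"))
  expect_true(all(m$negative$polarity == "neg"))
  expect_equal(sum(all_tr$is_internal_standard), 21)
  expect_equal(length(unique(all_tr$transition_id[all_tr$is_internal_standard])),
               21)
})

test_that("voltages carry the class rule with sign matching polarity", {
  m <- build_method()
  expect_true(all(m$negative$dp < 0 & m$negative$ce < 0))
  expect_true(all(m$positive$dp > 0 & m$positive$ce > 0))
})

test_that("transition lists export, round-trip, and honour the 1dp dialect", {
  tr <- build_class_transitions("LPC")
  path <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(tr, path, dialect = "exact")
  back <- read_transition_list(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$transition_id, tr$transition_id)
  expect_equal(back$q1, round(tr$q1, 4))
  expect_equal(back$dp, tr$dp)

  export_transition_list(tr, path, dialect = "1dp")
  lines <- readLines(path)
  expect_true(all(grepl(",\"184.1\",", lines[-1], fixed = TRUE)))

  # byte stability
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(tr, p2, dialect = "1dp")
  expect_identical(readLines(path), readLines(p2))

  # empty list gives a header-only file
  export_transition_list(tr[0, ], path)
  expect_equal(length(readLines(path)), 1)
})

test_that("neutral-loss product ions never exceed their precursor", {
  for (cl in c("DG", "TG", "MGDG", "DGDG", "MG")) {
    tr <- build_class_transitions(cl)
    expect_true(all(tr$q2 <= tr$q1 + 0.5), info = cl)
    expect_true(all(tr$q1 > 0 & tr$q2 > 0), info = cl)
  }
})
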