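test_that("amino-acid fractions count residues over chain length", {
  fr <- amino_acid_fractions(protein_record("p", "AAK"))
  expect_equal(fr[["A"]], 2 / 3)
  expect_equal(fr[["K"]], 1 / 3)
  expect_equal(sum(fr), 1)

  expect_equal(amino_acid_fractions(protein_record("p", "R"))[["R"]], 1)

  fr <- amino_acid_fractions(protein_record("p", "RKDE"))
  expect_equal(unname(fr[c("R", "K", "D", "E")]), rep(0.25, 4))

  expect_error(protein_record("p", ""), "empty")
})

test_that("nonstandard residues count in chain length but in no fraction", {
  expect_warning(fr <- amino_acid_fractions(protein_record("p", "AXK")),
                 "nonstandard")
  expect_equal(fr[["A"]], 1 / 3)
  expect_equal(sum(fr), 2 / 3)
})

test_that("exposure split uses chain length and closes to the total", {
  sp <- exposure_split_fractions(protein_record("p", "AK",
                                                exposure = c("B", "E")))
  expect_equal(sp$buried[["A"]], 0.5)
  expect_equal(sp$exposed[["A"]], 0)
  expect_equal(sp$exposed[["K"]], 0.5)

  sp <- exposure_split_fractions(protein_record("p", "LLLL",
                                                exposure = "BBBB"))
  expect_equal(sp$buried[["L"]], 1)
  expect_equal(sp$exposed[["L"]], 0)

  sp <- exposure_split_fractions(protein_record("p", "DKDK",
                                                exposure = "EEBB"))
  expect_equal(sp$exposed[["D"]], 0.25)
  expect_equal(sp$buried[["D"]], 0.25)
  expect_equal(sp$exposed[["K"]], 0.25)
  expect_equal(sp$buried[["K"]], 0.25)

  expect_error(exposure_split_fractions(protein_record("p", "AK")),
               "annotation required")

  set.seed(41)
  for (i in 1:20) {
    s <- random_peptide(sample(5:60, 1))
    lab <- paste0(sample(c("B", "E"), nchar(s), replace = TRUE),
                  collapse = "")
    r <- protein_record("p", s, exposure = lab)
    sp <- exposure_split_fractions(r)
    expect_equal(sp$buried + sp$exposed, amino_acid_fractions(r))
  }
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy(protein_record("p", "A")), 1.8)
  expect_equal(gravy(protein_record("p", "AILV")), 3.575)
  expect_equal(gravy(protein_record("p", strrep("W", 17))),
               gravy(protein_record("p", "W")))
  zero <- scale_config(hydropathy = setNames(rep(0, 20),
                                             names(kd_hydropathy)))
  expect_equal(gravy(protein_record("p", random_peptide(30)), zero), 0)
  expect_error(gravy(protein_record("p", "AXA")), "missing from hydropathy")
  expect_warning(g <- gravy(protein_record("p", "AXA"), on_missing = "skip"),
                 "skipped")
  expect_equal(g, 1.8)
})

test_that("side-chain entropy means follow the configured scale", {
  sc <- scale_config()
  expect_equal(sidechain_entropy(protein_record("p", strrep("Q", 9))),
               sc$sce[["Q"]])
  r <- protein_record("p", strrep("Q", 9), exposure = strrep("E", 9))
  expect_equal(sidechain_entropy(r, exposed_only = TRUE), sc$sce[["Q"]])

  r <- protein_record("p", "GK", exposure = "BE")
  expect_equal(sidechain_entropy(r, exposed_only = TRUE), sc$sce[["K"]])

  set.seed(42)
  s <- random_peptide(40)
  lab <- sample(c("B", "E"), 40, replace = TRUE)
  r <- protein_record("p", s, exposure = lab)
  chars <- strsplit(s, "")[[1]]
  expect_equal(sidechain_entropy(r), mean(sc$sce[chars]))
  expect_equal(sidechain_entropy(r, exposed_only = TRUE),
               mean(sc$sce[chars[lab == "E"]]))

  allb <- protein_record("p", "AK", exposure = "BB")
  expect_warning(v <- sidechain_entropy(allb, exposed_only = TRUE),
                 "no exposed")
  expect_true(is.na(v))
})

test_that("charge metrics follow the R/K/D/E count formulas", {
  m <- charge_metrics(protein_record("p", "RKDE"))
  expect_equal(unname(m), c(4, 0, 0, 1, 0, 0))

  m <- charge_metrics(protein_record("p", "RRKDA"))
  expect_equal(m[["numcharge"]], 4)
  expect_equal(m[["netcharge"]], 2)
  expect_equal(m[["absnetcharge"]], 2)
  expect_equal(m[["fracnumcharge"]], 0.8)
  expect_equal(m[["fracnetcharge"]], 0.4)

  m <- charge_metrics(protein_record("p", "GGGG"))
  expect_equal(unname(m), rep(0, 6))

  ## absolute value and dominance invariants on random peptides
  set.seed(43)
  for (i in 1:20) {
    m <- charge_metrics(protein_record("p", random_peptide(25)))
    expect_equal(m[["absnetcharge"]], abs(m[["netcharge"]]))
    expect_gte(m[["fracnumcharge"]], abs(m[["fracnetcharge"]]))
  }
})

test_that("isoelectric point is the root of the charge curve", {
  set.seed(44)
  for (i in 1:25) {
    r <- protein_record("p", random_peptide(sample(5:80, 1)))
    pi_hat <- isoelectric_point(r)
    expect_lt(abs(net_charge(r, pi_hat)), 1e-3)
  }
  ## monotonicity: adding a basic residue raises the pI
  for (i in 1:5) {
    s <- random_peptide(20)
    expect_gt(isoelectric_point(protein_record("p", paste0("K", s))),
              isoelectric_point(protein_record("p", s)))
  }
})

test_that("bisection pI agrees with the brute-force pH grid oracle", {
  peptides <- c("DDKK", "ACDEFGHIKLMNPQRSTVWY", "KKKKRRH", "DDDEEC",
                "MGSSHHHHHH", "WLVIF")
  for (s in peptides) {
    expect_lt(abs(isoelectric_point(protein_record("p", s)) - oracle_pi(s)),
              1e-3)
  }
  set.seed(45)
  for (i in 1:12) {
    s <- random_peptide(sample(8:40, 1))
    expect_lt(abs(isoelectric_point(protein_record("p", s)) - oracle_pi(s)),
              1e-3)
  }
})

test_that("disorder fraction is the labeled fraction", {
  expect_equal(disorder_fraction(protein_record("p", "AAAA",
                                                disorder = "OOOO")), 0)
  expect_equal(disorder_fraction(protein_record("p", "AAAA",
                                                disorder = "DDDD")), 1)
  expect_equal(disorder_fraction(
    protein_record("p", strrep("A", 10),
                   disorder = "DDDOOOOOOO")), 0.3)
  expect_error(disorder_fraction(protein_record("p", "AA")),
               "annotation required")
})

test_that("rare-codon split classifies codons and closes to the total", {
  sc <- scale_config()
  sp <- rare_codon_split(protein_record("p", "RR", cds = "CGTAGA"), sc)
  expect_equal(sp["R", "rare"], 0.5)
  expect_equal(sp["R", "common"], 0.5)

  sp <- rare_codon_split(protein_record("p", "GGSS",
                                        cds = "GGTGGCAGTAGC"), sc)
  expect_equal(unname(c(sp)), rep(0, 8))

  expect_error(protein_record("p", "I", cds = "ATG"),
               "codon 1 .* translates to M")

  ## closure on a random CDS
  set.seed(46)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  cds <- paste0(sample(sense, 40, replace = TRUE), collapse = "")
  aa <- paste0(gc[substring(cds, seq(1, 118, 3), seq(3, 120, 3))],
               collapse = "")
  r <- protein_record("p", aa, cds = cds)
  sp <- rare_codon_split(r, sc)
  fr <- amino_acid_fractions(r)
  for (a in c("R", "I", "L", "P"))
    expect_equal(sp[a, "rare"] + sp[a, "common"], fr[[a]])
})

test_that("the full feature vector matches the standalone operations", {
  set.seed(47)
  s <- random_peptide(60)
  expo <- paste0(sample(c("B", "E"), 60, replace = TRUE), collapse = "")
  diso <- paste0(sample(c("O", "D"), 60, replace = TRUE), collapse = "")
  gc <- Biostrings::GENETIC_CODE
  codons_of <- split(names(gc)[gc != "*"], gc[gc != "*"])
  cds <- paste0(vapply(strsplit(s, "")[[1]],
                       function(a) sample(codons_of[[a]], 1), ""),
                collapse = "")
  r <- protein_record("gold", s, cds = cds, exposure = expo, disorder = diso)
  sc <- scale_config()
  fv <- compute_feature_vector(r, sc)

  expect_length(setdiff(core_parameter_names(), names(fv)), 0)
  fr <- amino_acid_fractions(r)
  sp <- exposure_split_fractions(r)
  for (a in names(kd_hydropathy)) {
    expect_equal(fv[[tolower(a)]], fr[[a]])
    expect_equal(fv[[paste0(tolower(a), "b")]], sp$buried[[a]])
    expect_equal(fv[[paste0(tolower(a), "e")]], sp$exposed[[a]])
  }
  expect_equal(fv[["gravy"]], gravy(r, sc))
  expect_equal(fv[["sce"]], sidechain_entropy(r, sc))
  expect_equal(fv[["esce"]], sidechain_entropy(r, sc, exposed_only = TRUE))
  cm <- charge_metrics(r)
  for (nm in names(cm)) expect_equal(fv[[nm]], cm[[nm]])
  expect_equal(fv[["diso"]], disorder_fraction(r))
  expect_equal(fv[["length"]], 60)
  expect_lt(abs(fv[["pi"]] - isoelectric_point(r, sc)), 1e-4)
  rc <- rare_codon_split(r, sc)
  for (a in c("r", "i", "l", "p")) {
    expect_equal(fv[[paste0(a, "_rare")]], rc[toupper(a), "rare"])
    expect_equal(fv[[paste0(a, "_common")]], rc[toupper(a), "common"])
  }
})

test_that("missing annotations yield absent parameters, not zeros", {
  fv <- compute_feature_vector(protein_record("p", "ACDEFG"))
  absent <- attr(fv, "absent")
  expect_true(all(c("ab", "ae", "esce", "diso") %in% absent))
  expect_true(all(is.na(fv[absent])))
  expect_false(anyNA(fv[c("a", "gravy", "sce", "fracnumcharge", "pi")]))
})

test_that("fractional parameters are invariant under sequence duplication", {
  set.seed(48)
  s <- random_peptide(35)
  expo <- paste0(sample(c("B", "E"), 35, replace = TRUE), collapse = "")
  diso <- paste0(sample(c("O", "D"), 35, replace = TRUE), collapse = "")
  r1 <- protein_record("p", s, exposure = expo, disorder = diso)
  r2 <- protein_record("p", paste0(s, s),
                       exposure = paste0(expo, expo),
                       disorder = paste0(diso, diso))
  f1 <- compute_feature_vector(r1)
  f2 <- compute_feature_vector(r2)
  doubling <- c("length", "numcharge", "netcharge", "absnetcharge")
  for (nm in names(f1)) {
    if (nm %in% doubling) expect_equal(f2[[nm]], 2 * f1[[nm]], info = nm)
    else if (nm == "pi") next   # termini weight halves; pI shifts slightly
    else if (!is.na(f1[[nm]]))
      expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-3, info = nm)
  }
})

test_that("the vectorized feature table matches per-record computation", {
  set.seed(49)
  n <- 8
  aa <- setNames(vapply(1:n, function(i) random_peptide(sample(20:50, 1)),
                        ""), paste0("q", 1:n))
  ann <- annotate_baseline(aa)
  tab <- feature_table(aa, exposure = ann$exposure, disorder = ann$disorder)
  expect_equal(tab$id, names(aa))
  for (i in c(1, 4, n)) {
    r <- protein_record(names(aa)[i], aa[[i]],
                        exposure = ann$exposure[[i]],
                        disorder = ann$disorder[[i]])
    fv <- compute_feature_vector(r)
    row <- unlist(tab[i, -1])
    expect_equal(unname(row[core_parameter_names()]),
                 unname(fv[core_parameter_names()]), tolerance = 1e-12)
  }
})
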