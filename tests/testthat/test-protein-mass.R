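test_that("average mass sums residue masses plus one water", {
  expect_equal(averageMass("G"), 75.0672, tolerance = 1e-6)
  expect_error(averageMass("MGX"), "unknown residue")
  expect_error(averageMass(""), "empty")

  ## additivity: one water per peptide bond
  set.seed(3)
  aa <- names(massConstants()$residues)
  for (i in 1:5) {
    s1 <- paste(sample(aa, 12, TRUE), collapse = "")
    s2 <- paste(sample(aa, 7, TRUE), collapse = "")
    expect_equal(averageMass(paste0(s1, s2)),
                 averageMass(s1) + averageMass(s2) - massConstants()$water,
                 tolerance = 1e-9)
  }

  ## random 100-mer against an independent per-residue summation
  s <- paste(sample(aa, 100, TRUE), collapse = "")
  tbl <- massConstants()$residues
  manual <- massConstants()$water
  for (ch in strsplit(s, "")[[1]]) manual <- manual + tbl[[ch]]
  expect_equal(averageMass(s), manual, tolerance = 1e-6)
})

test_that("N-terminal Met excision follows the small-residue rule", {
  r <- applyNTermRule(c("MGK", "MKG", "AGK", "MAVR", "MQX"))
  expect_equal(r$met_loss, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(r$sequence, c("GK", "MKG", "AGK", "AVR", "MQX"))
  ## second residue K keeps Met (as for subunits L36/L34);
  ## second residue A loses it (as for L33/L32)
  expect_false(applyNTermRule("MKIRPS")$met_loss)
  expect_true(applyNTermRule("MASFE")$met_loss)
})

test_that("mass prediction applies the rule before the mass", {
  pm <- predictMasses(c(p1 = "MGK", p2 = "MKG"))
  expect_equal(nrow(pm), 2L)
  expect_true(pm$met_loss[1]); expect_false(pm$met_loss[2])
  expect_equal(pm$theoretical_mass[1], averageMass("GK"))
  expect_equal(pm$theoretical_mass[2], averageMass("MKG"))
  expect_equal(pm$second_residue, c("G", "K"))

  aas <- Biostrings::AAStringSet(c(a = "MGGK", b = "MW"))
  expect_equal(nrow(predictMasses(aas)), 2L)
})

test_that("annotation picks the minimal-|error| hypothesis within tolerance", {
  recs <- am1RibosomalProteins()
  ## unmodified match: L36 observed in the whole-cell channel
  ann <- annotatePeaks(4993.07, recs, tolerance = 5)
  expect_identical(ann$matches$subunit, "L36")
  expect_equal(ann$matches$error, -1.87, tolerance = 1e-9)
  expect_identical(ann$matches$modification, "none")

  ## methylated L33: error reported against the unmodified mass is 13.89
  ann2 <- annotatePeaks(6278.49, recs, tolerance = 5, modifications = TRUE)
  expect_identical(ann2$matches$subunit, "L33")
  expect_identical(ann2$matches$modification, "methylation")
  expect_equal(ann2$matches$error_vs_unmodified, 13.89, tolerance = 1e-9)
  expect_lt(abs(ann2$matches$error), 5)

  ## with modifications off the peak is unmatched
  ann3 <- annotatePeaks(6278.49, recs, tolerance = 5, modifications = FALSE)
  expect_equal(nrow(ann3$matches), 0L)
  expect_equal(ann3$unmatched, 6278.49)

  ## far-away peak lands in the unmatched list
  ann4 <- annotatePeaks(c(1000, 4993.07), recs, tolerance = 5)
  expect_equal(ann4$unmatched, 1000)
  expect_equal(nrow(ann4$matches), 1L)
})

test_that("annotation prefers the nearer unmodified neighbour over a modified one", {
  recs <- am1RibosomalProteins()
  ## 13716.81 sits 1.53 Da from S13 unmodified and 4.55 Da from
  ## beta-methylthiolated S12: S13 must win
  ann <- annotatePeaks(13716.81, recs, tolerance = 5, modifications = TRUE)
  expect_identical(ann$matches$subunit, "S13")
  ## 13719.69 is nearer the beta-methylthiolated S12 hypothesis
  ann2 <- annotatePeaks(13719.69, recs, tolerance = 5, modifications = TRUE)
  expect_identical(ann2$matches$subunit, "S12")
  expect_identical(ann2$matches$modification, "beta_methylthiolation")
})

test_that("annotation is stable under peak-order permutation", {
  recs <- am1RibosomalProteins()
  obs <- recs$wcms_mz[!is.na(recs$wcms_mz)]
  a1 <- annotatePeaks(obs, recs)
  a2 <- annotatePeaks(rev(obs), recs)
  k1 <- a1$matches[order(a1$matches$observed_mz), ]
  k2 <- a2$matches[order(a2$matches$observed_mz), ]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("detection report counts distinct proteins per channel", {
  recs <- am1RibosomalProteins()
  annW <- annotatePeaks(recs$wcms_mz[!is.na(recs$wcms_mz)], recs)
  rep0 <- detectionReport(list(wcms = annW), recs)
  expect_equal(rep0$summary$proteins_detected,
               length(unique(annW$matches$id)))
  expect_true(all(rep0$undetected_in_range$wcms %in% recs$id))

  empty <- annotatePeaks(numeric(0), recs)
  repE <- detectionReport(list(wcms = empty), recs)
  expect_equal(repE$summary$proteins_detected, 0L)
  expect_equal(length(repE$undetected_in_range$wcms), repE$n_in_range)
})

test_that("shared-mass report exposes cross-species identical masses", {
  tabs <- list(spA = c(5000.00, 7000.00, 9000.00),
               spB = c(5000.001, 8000.00),
               spC = c(8000.002, 12000.00))
  rep <- sharedMassReport(tabs, tolerance = 0.005)
  expect_equal(nrow(rep), 2L)
  expect_identical(rep$species, c("spA,spB", "spB,spC"))
  ## no mass is shared across all three species
  expect_false(any(rep$species == "spA,spB,spC"))
})

test_that("the packaged reference table is complete and consistent", {
  recs <- am1RibosomalProteins()
  expect_equal(nrow(recs), 54L)
  expect_false(anyDuplicated(recs$id) > 0)
  expect_equal(sum(!is.na(recs$wcms_mz)), 19L)
  expect_equal(sum(!is.na(recs$ribosome_mz)), 23L)
  ## printed errors are observed minus theoretical (to printing precision)
  w <- !is.na(recs$wcms_mz) & recs$remark == ""
  expect_equal(recs$wcms_mz[w] - recs$theoretical_mass[w],
               recs$wcms_error[w], tolerance = 0.011)
})
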