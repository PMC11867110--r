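test_that("barcode designs validate their geometry", {
  d <- toyDesign(2)
  expect_s4_class(d, "BarcodeDesign")
  expect_equal(numTargets(d), 2L)
  expect_equal(cutSites(d), c(2L, 6L))
  ## offset3p convention stores absolute bonds
  d2 <- barcodeDesign("ACGTACGTAC", rbind(c(0, 5), c(5, 10)), c(2, 2),
                      cutConvention = "offset3p")
  expect_equal(cutSites(d2), c(3L, 8L))
  expect_error(barcodeDesign("ACGT", rbind(c(0, 4)), 5), "cut position")
  expect_error(barcodeDesign("ACNT", rbind(c(0, 4)), 2), "A/C/G/T")
  expect_error(barcodeDesign("ACGTACGT", rbind(c(0, 5), c(4, 8)), c(2, 6)),
               "non-overlapping")
})

test_that("design JSON round-trips", {
  d <- v7BarcodeDesign(4)
  f <- withr::local_tempfile(fileext = ".json")
  writeBarcodeDesign(d, f)
  d2 <- readBarcodeDesign(f)
  expect_equal(barcodeSequence(d2), barcodeSequence(d))
  expect_equal(targetBounds(d2), targetBounds(d))
  expect_equal(cutSites(d2), cutSites(d))
})

test_that("indels validate bounds and target spans", {
  d <- toyDesign(2)
  ind <- indel(1, 2, design = d)       # covers cut bond 2
  expect_equal(c(ind$tmin, ind$tmax), c(1L, 1L))
  expect_error(indel(0, 100, design = d), "outside the barcode")
  expect_error(indel(3, 0, "", design = d), "delete or insert")
  ## a deletion that covers no cut bond is not a valid editing outcome
  expect_error(indel(7, 1, design = toyDesign(2, 8L, 2L)), "no target cut")
})

test_that("allele table parsing maps fields and counts indels", {
  d <- toyDesign(2, 6L, 2L)   # cuts at bonds 4 and 10
  txt <- c("cell_id\tindels",
           "cellA\t",
           "cellB\t3:2::1:1,9:2::2:2")
  aln <- parseAlleleTable(txt, d)
  expect_s4_class(aln, "BarcodeAlignment")
  expect_equal(cellIds(aln), c("cellA", "cellB"))
  expect_equal(vapply(alleles(aln), length, 0L), c(0L, 2L))
  ind <- alleles(aln)[[2L]][[1L]]
  expect_equal(ind$start, 3L)
  expect_equal(ind$del, 2L)
  expect_equal(ind$insert, "")
  ## malformed rows carry line numbers; bad coordinates carry cell ids
  expect_error(parseAlleleTable(c("cell_id\tindels", "c1\t1:2:x"), d),
               "line 2")
  expect_error(parseAlleleTable(c("cell_id\tindels", "c1\t90:5::1:1"), d),
               "cell 'c1'")
  expect_error(parseAlleleTable(c("bad\theader"), d), "line 1")
})

test_that("write -> parse is the identity on valid alignments", {
  set.seed(21)
  inst <- randomToyInstance(m = 3, nLeaves = 4, withInserts = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAlleleTable(inst$aln, f)
  back <- parseAlleleTable(f, inst$design)
  expect_equal(cellIds(back), cellIds(inst$aln))
  k1 <- vapply(alleles(inst$aln), gestaltphylo:::alleleKey, "")
  k2 <- vapply(alleles(back), gestaltphylo:::alleleKey, "")
  expect_equal(k2, k1)
})

test_that("normalization merges indels sharing a target and is idempotent", {
  d <- toyDesign(2, 6L, 2L)           # cuts at 4 and 10
  ## two deletions abutting at the cut bond of target 1
  raw <- list(indel(2, 2, design = d), indel(4, 3, design = d))
  al <- normalizeAllele(raw, d)
  expect_length(al, 1L)
  expect_equal(al[[1L]]$start, 2L)
  expect_equal(al[[1L]]$del, 5L)
  expect_equal(c(al[[1L]]$tmin, al[[1L]]$tmax), c(1L, 1L))
  ## idempotent
  al2 <- normalizeAllele(al, d)
  expect_equal(gestaltphylo:::alleleKey(al2), gestaltphylo:::alleleKey(al))
  ## disjoint indels in different targets are retained
  raw2 <- list(indel(3, 2, design = d), indel(9, 2, design = d))
  expect_length(normalizeAllele(raw2, d), 2L)
  ## single indel unchanged
  expect_length(normalizeAllele(list(indel(3, 2, design = d)), d), 1L)
  ## merged inserts concatenate in barcode order
  raw3 <- list(indel(4, 3, "GG", design = d), indel(2, 2, "AA", design = d))
  al3 <- normalizeAllele(raw3, d)
  expect_equal(al3[[1L]]$insert, "AAGG")
})

test_that("merging never reactivates a target", {
  d <- toyDesign(3)
  set.seed(4)
  for (rep in 1:20) {
    inst <- randomToyInstance(m = 3, nLeaves = 3)
    for (al in alleles(inst$aln)) {
      if (!length(al)) next
      pre <- targetStatus(al, inst$design)
      post <- targetStatus(normalizeAllele(al, inst$design), inst$design)
      expect_true(all(post <= pre))   # merging never reactivates
    }
  }
})

test_that("target status follows footprint intersection", {
  d10 <- v7BarcodeDesign(10)
  expect_equal(targetStatus(allele(list()), d10), rep(TRUE, 10))
  ## focal deletion in target 5 of the 10 x 23 bp design: one inactive
  c5 <- cutSites(d10)[5L]
  al <- allele(list(indel(c5 - 2L, 4L, design = d10)), d10)
  st <- targetStatus(al, d10)
  expect_equal(which(!st), 5L)
  ## indel spanning targets 1-2
  d <- toyDesign(3)
  sp <- allele(list(indel(1, 6, design = d)), d)
  expect_equal(targetStatus(sp, d), c(FALSE, FALSE, TRUE))
  ## pure insertion deactivates only the target holding its bond
  ins <- allele(list(indel(cutSites(d)[2L], 0, "AT", design = d)), d)
  expect_equal(targetStatus(ins, d), c(TRUE, FALSE, TRUE))
})

test_that("applyAllele reconstructs the edited sequence", {
  d <- toyDesign(2, 6L, 2L)
  expect_equal(applyAllele(d, allele(list())), barcodeSequence(d))
  del <- allele(list(indel(3, 3, design = d)), d)
  expect_equal(nchar(applyAllele(d, del)), nchar(barcodeSequence(d)) - 3L)
  expect_equal(applyAllele(d, del),
               paste0(substr(barcodeSequence(d), 1, 3),
                      substr(barcodeSequence(d), 7, 12)))
  ins <- allele(list(indel(4, 0, "AT", design = d)), d)
  expect_equal(nchar(applyAllele(d, ins)), nchar(barcodeSequence(d)) + 2L)
})

test_that("the shipped simulated example data load and evaluate", {
  design <- readBarcodeDesign(system.file("extdata", "v7_4target_design.json",
                                          package = "gestaltphylo"))
  params <- readEditingParams(system.file("extdata", "example_params.json",
                                          package = "gestaltphylo"))
  aln <- parseAlleleTable(system.file("extdata", "example_alleles.tsv",
                                      package = "gestaltphylo"), design)
  phy <- ape::read.tree(system.file("extdata", "example_tree.nwk",
                                    package = "gestaltphylo"))
  expect_equal(numTargets(design), 4L)
  expect_setequal(cellIds(aln), phy$tip.label)
  ll <- treeLogLikelihood(phy, aln, params)
  expect_true(is.finite(ll) && ll < 0)
})
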