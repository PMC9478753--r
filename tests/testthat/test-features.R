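test_that("interval density counts midpoints and splits coverage at bin edges", {
  g <- tiny_grid(10)
  feats <- tibble::tibble(chrom = "chr1",
                          start = c(710000, 720000, 790000, 150000),
                          end = c(712000, 722000, 791000, 250000))
  cnt <- bin_interval_density(feats, g, "count")
  expect_equal(cnt$value[8], 3)   # three midpoints in bin 7 (0-based)
  expect_equal(cnt$value[3], 1)   # spanning interval assigned to its midpoint bin

  cov <- bin_interval_density(feats, g, "coverage")
  expect_equal(cov$value[2], 50000)  # 150k-200k of the spanning interval
  expect_equal(cov$value[3], 50000)  # 200k-250k

  # conservation: total coverage equals total interval length
  set.seed(31)
  s <- sort(sample(0:990000, 50))
  rnd <- tibble::tibble(chrom = "chr1", start = s,
                        end = pmin(s + sample(1:30000, 50, TRUE), 1e6))
  covr <- bin_interval_density(rnd, g, "coverage")
  expect_equal(sum(covr$value), sum(rnd$end - rnd$start))

  expect_error(bin_interval_density(
    tibble::tibble(chrom = "chr9", start = 0, end = 10), g), "chromosome")
  expect_error(bin_interval_density(
    tibble::tibble(chrom = "chr1", start = 990000, end = 2e6), g), "off chromosome")
})

test_that("GC content excludes ambiguous bases", {
  g <- build_genome(1, 12, 4)
  expect_equal(gc_per_bin(c(chr1 = "ATGCATGCATGC"), g)$value, rep(0.5, 3))
  expect_equal(gc_per_bin(c(chr1 = "AAAAANNGGGGG"), g)$value[1], 0)
  # "ANNG": one of the two informative bases is G/C
  expect_equal(gc_per_bin(c(chr1 = "ANNGATGCNNNN"), g)$value,
               c(0.5, 0.5, NA))
  expect_error(gc_per_bin(c(chr1 = "ATGC"), g), "length mismatch")
})

test_that("signal sums are bin-split exactly and conserve totals", {
  g <- tiny_grid(10)
  cov <- tibble::tibble(chrom = "chr1", start = 20000, end = 30000, value = 2)
  expect_equal(bin_signal_sum(cov, g)$value[1], 20000)

  strad <- tibble::tibble(chrom = "chr1", start = 95000, end = 105000,
                          value = 3)
  bs <- bin_signal_sum(strad, g)
  expect_equal(bs$value[1:2], c(15000, 15000))

  set.seed(33)
  starts <- seq(0, 990000, by = 10000)
  rnd <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 7000,
                        value = runif(length(starts), 0, 5))
  expect_equal(sum(bin_signal_sum(rnd, g)$value),
               sum(rnd$value * (rnd$end - rnd$start)))

  bad <- tibble::tibble(chrom = "chr1", start = c(0, 5000),
                        end = c(10000, 15000), value = 1)
  expect_error(bin_signal_sum(bad, g), "overlapping")
})

test_that("input subtraction scales the control to the ChIP total", {
  g <- tiny_grid(5)
  chip <- binned_signal(g, c(10, 8, 6, 4, 2), "mark")
  expect_equal(subtract_input(chip, chip)$value, rep(0, 5))

  half <- binned_signal(g, c(5, 4, 3, 2, 1), "input")
  expect_equal(subtract_input(chip, half)$value, rep(0, 5))  # scale factor 2

  inp <- binned_signal(g, c(3, 3, 3, 3, 3) * 2, "input")
  out <- subtract_input(chip, inp)
  expect_equal(out$value, chip$value - 6)
  expect_true(any(out$value < 0))  # negatives retained

  zero <- binned_signal(g, rep(0, 5), "input")
  expect_warning(res <- subtract_input(chip, zero), "zero")
  expect_equal(res$value, chip$value)
  expect_false(attr(res, "input_subtracted"))
})

test_that("open-chromatin masking restricts signal to DHS bp", {
  g <- tiny_grid(4)
  track <- tibble::tibble(chrom = "chr1",
                          start = c(0, 100000, 200000, 300000),
                          end = c(100000, 200000, 300000, 400000),
                          value = c(1, 2, 3, 4))
  # peaks covering a whole bin leave it unchanged; bins without peaks drop to 0
  dhs <- tibble::tibble(chrom = "chr1", start = 0, end = 100000)
  out <- mask_to_open_chromatin(track, dhs, g, "raw")
  expect_equal(out$value, c(100000, 0, 0, 0))

  # peaks covering exactly half of every interval halve every bin
  dhs_half <- tibble::tibble(chrom = "chr1",
                             start = seq(0, 300000, 100000),
                             end = seq(0, 300000, 100000) + 50000)
  out_half <- mask_to_open_chromatin(track, dhs_half, g, "raw")
  full <- bin_signal_sum(track, g)
  expect_equal(out_half$value, full$value / 2)

  # binned mode multiplies by the open fraction
  sig <- binned_signal(g, c(8, 8, 8, 8))
  outb <- mask_to_open_chromatin(sig, dhs_half, g, "binned")
  expect_equal(outb$value, rep(4, 4))

  expect_warning(res <- mask_to_open_chromatin(track, dhs[0, ], g, "raw"),
                 "empty")
  expect_true(all(is.na(res$value)))
})

test_that("annotation composition follows the precedence rule and sums to one", {
  g <- tiny_grid(4)
  cats <- dplyr::mutate(tibble::as_tibble(g),
                        category = c("CE", "CE", "CL", "CL"))
  # intergenic-only category
  genes <- tibble::tibble(chrom = "chr1", start = 50000, end = 150000,
                          strand = "+")
  comp <- annotation_composition(cats, genes, promoter_flank = 1000)
  cl <- comp[comp$category == "CL", ]
  expect_equal(unlist(cl[, c("promoter", "exon", "intron", "intergenic")]),
               c(promoter = 0, exon = 0, intron = 0, intergenic = 1))
  expect_equal(rowSums(comp[, c("promoter", "exon", "intron", "intergenic")]),
               rep(1, nrow(comp)), tolerance = 1e-9)

  # promoter takes precedence over exon inside the gene span
  ce <- comp[comp$category == "CE", ]
  expect_equal(ce$promoter, 2000 / 200000)       # TSS +/- 1 kb at 50 kb
  expect_equal(ce$exon, (100000 - 1000) / 200000)  # gene minus promoter bp
  expect_equal(ce$intron, 0)

  # with explicit exons the remainder of the gene body is intronic
  exons <- tibble::tibble(chrom = "chr1", start = c(50000, 140000),
                          end = c(60000, 150000))
  comp2 <- annotation_composition(cats, genes, exons, promoter_flank = 1000)
  ce2 <- comp2[comp2$category == "CE", ]
  expect_gt(ce2$intron, 0)
  expect_equal(rowSums(comp2[, c("promoter", "exon", "intron", "intergenic")]),
               rep(1, nrow(comp2)), tolerance = 1e-9)

  # random annotations still normalize
  set.seed(35)
  rg <- tibble::tibble(chrom = "chr1",
                       start = sort(sample(0:350000, 5)),
                       end = 0, strand = sample(c("+", "-"), 5, TRUE))
  rg$end <- rg$start + sample(5000:40000, 5)
  comp3 <- annotation_composition(cats, rg)
  expect_equal(rowSums(comp3[, c("promoter", "exon", "intron", "intergenic")]),
               rep(1, nrow(comp3)), tolerance = 1e-9)
})

test_that("anchored profiles are oriented by strand", {
  track <- tibble::tibble(chrom = "chr1", start = 10100, end = 10150,
                          value = 4)
  plus <- tibble::tibble(chrom = "chr1", pos = 10000, strand = "+")
  prof <- anchored_profile(track, plus, flank = 200, step = 50)
  expect_equal(prof$mean_signal[prof$offset == 100], 4)
  expect_equal(sum(prof$mean_signal != 0), 1)

  # same spike 100 bp downstream of a minus-strand anchor
  track_m <- tibble::tibble(chrom = "chr1", start = 9851, end = 9901,
                            value = 4)
  minus <- tibble::tibble(chrom = "chr1", pos = 10000, strand = "-")
  prof_m <- anchored_profile(track_m, minus, flank = 200, step = 50)
  expect_equal(prof_m$mean_signal[prof_m$offset == 100], 4)

  # constant track gives a flat profile at the constant
  const <- tibble::tibble(chrom = "chr1", start = 0, end = 50000, value = 2.5)
  profc <- anchored_profile(const, plus, flank = 500, step = 100)
  expect_true(all(profc$mean_signal == 2.5))

  # mirror symmetry: flipping the strand and mirroring the track about the
  # anchor leaves the oriented profile unchanged
  expect_equal(prof$mean_signal, prof_m$mean_signal)

  expect_error(anchored_profile(track, plus[0, ]), "anchors")
  expect_error(anchored_profile(track, plus, flank = 130, step = 50),
               "multiple")
})
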