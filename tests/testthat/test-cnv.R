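sim_depth <- function(n_samples = 24, mu = 350, size = 200, seed = 1) {
  targets <- test_panel()$regions
  withr::with_seed(seed, {
    d <- matrix(rnbinom(nrow(targets) * n_samples, mu = mu, size = size),
                ncol = n_samples,
                dimnames = list(NULL, sprintf("T%02d", seq_len(n_samples))))
    depth_matrix(targets, d)
  })
}

test_that("normalization has the expected fixed points", {
  targets <- test_panel()$regions
  m <- depth_matrix(targets, matrix(100, nrow(targets), 10,
                                    dimnames = list(NULL, paste0("s", 1:10))))
  expect_true(all(abs(normalize_depth(m) - 1) < 1e-12))
  # a uniformly 2x deeper sample still normalizes to 1 (library size)
  d <- m$depth
  d[, 3] <- d[, 3] * 2
  expect_true(all(abs(normalize_depth(depth_matrix(targets, d)) - 1) <
                    1e-12))
})

test_that("a planted exon-level gain lands near its planted ratio", {
  m <- sim_depth(seed = 42)
  i <- which(m$targets$label == "BMPR2_ex02")
  m$depth[i, 3] <- round(m$depth[i, 3] * 1.5)
  r <- normalize_depth(m)
  expect_lt(abs(r[i, 3] - 1.5), 0.05 + 0.05)  # planted-truth tolerance
})

test_that("zero-median samples are excluded; tiny cohorts error", {
  targets <- test_panel()$regions
  d <- matrix(100, nrow(targets), 3,
              dimnames = list(NULL, c("a", "b", "c")))
  d[, 2] <- 0
  expect_warning(r <- normalize_depth(depth_matrix(targets, d)), "zero")
  expect_equal(colnames(r), c("a", "c"))
  d2 <- d[, 1:2]
  expect_error(suppressWarnings(normalize_depth(depth_matrix(targets, d2))),
               "fewer than 2")
})

test_that("single planted duplication yields exactly one gain call", {
  m <- sim_depth(seed = 7)
  i <- which(m$targets$label == "BMPR2_ex02")
  m$depth[i, 5] <- round(m$depth[i, 5] * 1.5)
  calls <- call_cnvs(normalize_depth(m), m$targets)
  hit <- calls[calls$sample_id == "T05" & calls$gene == "BMPR2", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$kind, "gain")
  expect_equal(hit$targets, "BMPR2_ex02")
  expect_gt(hit$ratio, 1.35)
  expect_lte(nrow(calls), 2L)  # at most stray noise beyond the plant
})

test_that("a flat cohort yields zero calls", {
  m <- sim_depth(seed = 9)
  calls <- call_cnvs(normalize_depth(m), m$targets)
  expect_lte(nrow(calls), 1L)
})

test_that("a whole-gene heterozygous deletion merges into one loss call", {
  m <- sim_depth(seed = 21)
  i <- which(m$targets$gene == "EIF2AK4")
  m$depth[i, 10] <- round(m$depth[i, 10] * 0.5)
  calls <- call_cnvs(normalize_depth(m), m$targets)
  hit <- calls[calls$sample_id == "T10" & calls$gene == "EIF2AK4", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$kind, "loss")
  expect_equal(hit$n_targets, length(i))
  expect_lt(hit$ratio, 0.65)
})

test_that("permuting sample order permutes calls identically", {
  m <- sim_depth(seed = 33)
  i <- which(m$targets$label == "TBX4_ex02")
  m$depth[i, 2] <- round(m$depth[i, 2] * 0.5)
  calls <- call_cnvs(normalize_depth(m), m$targets)
  perm <- rev(seq_along(m$samples))
  m2 <- depth_matrix(m$targets, m$depth[, perm])
  calls2 <- call_cnvs(normalize_depth(m2), m$targets)
  o1 <- calls[order(calls$sample_id, calls$targets), ]
  o2 <- calls2[order(calls2$sample_id, calls2$targets), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("small cohorts are flagged low-confidence", {
  m <- sim_depth(n_samples = 5, seed = 3)
  i <- which(m$targets$label == "GDF2_ex01")
  m$depth[i, 1] <- round(m$depth[i, 1] * 2.5)
  calls <- call_cnvs(normalize_depth(m), m$targets)
  expect_gte(nrow(calls), 1L)
  expect_true(all(calls$low_confidence))
})

test_that("depth matrices round-trip through TSV", {
  m <- sim_depth(n_samples = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(m, path)
  m2 <- read_depth_matrix(path)
  expect_equal(m2$targets$label, m$targets$label)
  expect_equal(unname(m2$depth), unname(m$depth))
})
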