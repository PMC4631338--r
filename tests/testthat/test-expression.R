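# Differential expression and co-expression calls.

.toy_expr <- function(n_genes = 20, n = 5, seed = 1) {
  set.seed(seed)
  meta <- data.frame(
    sample_id = c(sprintf("GK_liver_t1_r%d", 1:n),
                  sprintf("WISTAR_liver_t1_r%d", 1:n)),
    strain = rep(c("GK", "WISTAR"), each = n),
    tissue = "liver", time = 1, stringsAsFactors = FALSE
  )
  exprs <- matrix(rlnorm(n_genes * 2 * n, meanlog = 7, sdlog = 0.3),
                  nrow = n_genes,
                  dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                  meta$sample_id))
  list(exprs = exprs, meta = meta)
}

test_that("a planted 4-fold gene is called DE and identical groups are not", {
  d <- .toy_expr(seed = 2)
  d$exprs["G001", d$meta$strain == "GK"] <-
    4 * d$exprs["G001", d$meta$strain == "WISTAR"] *
    exp(rnorm(5, 0, 0.05))
  d$exprs["G002", d$meta$strain == "GK"] <-
    d$exprs["G002", d$meta$strain == "WISTAR"]
  res <- differential_expression(d$exprs, d$meta, "liver", 1,
                                 "GK", "WISTAR")
  expect_true(res$is_de[res$gene == "G001"])
  expect_false(res$is_de[res$gene == "G002"])
  expect_gt(res$fold_change[res$gene == "G001"], 2)
})

test_that("fold change is direction-symmetric under label swap", {
  d <- .toy_expr(seed = 3)
  a <- differential_expression(d$exprs, d$meta, "liver", 1, "GK", "WISTAR")
  b <- differential_expression(d$exprs, d$meta, "liver", 1, "WISTAR", "GK")
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  expect_equal(a$is_de, b$is_de)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("DE decisions are invariant to sample order", {
  d <- .toy_expr(seed = 4)
  a <- differential_expression(d$exprs, d$meta, "liver", 1, "GK", "WISTAR")
  perm <- sample(ncol(d$exprs))
  b <- differential_expression(d$exprs[, perm], d$meta, "liver", 1,
                               "GK", "WISTAR")
  expect_equal(a$p_value, b$p_value)
})

test_that("zero-variance degenerate genes are handled by the stated rules", {
  d <- .toy_expr(seed = 5)
  d$exprs["G001", ] <- 100              # equal constants: p = 1
  d$exprs["G002", d$meta$strain == "GK"] <- 300
  d$exprs["G002", d$meta$strain == "WISTAR"] <- 100  # unequal: p = 0, FC 3
  res <- differential_expression(d$exprs, d$meta, "liver", 1,
                                 "GK", "WISTAR")
  expect_equal(res$p_value[res$gene == "G001"], 1)
  expect_equal(res$p_value[res$gene == "G002"], 0)
  expect_true(res$is_de[res$gene == "G002"])
})

test_that("log-scale matrices use 2^(mean difference) as fold change", {
  d <- .toy_expr(seed = 6)
  lg <- log2(d$exprs)
  res <- differential_expression(lg, d$meta, "liver", 1, "GK", "WISTAR",
                                 log_scale = TRUE)
  gk <- d$meta$sample_id[d$meta$strain == "GK"]
  wi <- d$meta$sample_id[d$meta$strain == "WISTAR"]
  expect_equal(res$fold_change[1],
               2^(mean(lg["G001", gk]) - mean(lg["G001", wi])))
})

.dc_expr <- function(rho_case, rho_control, n = 20, n_bg = 4, seed = 8) {
  set.seed(seed)
  meta <- data.frame(
    sample_id = c(sprintf("GK_liver_t1_r%d", 1:n),
                  sprintf("WISTAR_liver_t1_r%d", 1:n)),
    strain = rep(c("GK", "WISTAR"), each = n),
    tissue = "liver", time = 1, stringsAsFactors = FALSE
  )
  gen_pair <- function(rho, m) {
    ep <- rnorm(m); eg <- rho * ep + sqrt(1 - rho^2) * rnorm(m)
    rbind(ep, eg)
  }
  pc <- gen_pair(rho_case, n); pw <- gen_pair(rho_control, n)
  exprs <- rbind(
    cbind(pc, pw) * 50 + 500,
    matrix(rlnorm(n_bg * 2 * n, 6, 0.3), nrow = n_bg)
  )
  rownames(exprs) <- c("PARTNER", "DCGENE", sprintf("BG%d", seq_len(n_bg)))
  colnames(exprs) <- meta$sample_id
  list(exprs = exprs, meta = meta)
}

test_that("a correlation flip between conditions is called DC", {
  d <- .dc_expr(0.9, -0.9)
  res <- differential_coexpression(d$exprs, d$meta, "liver", 1,
                                   "GK", "WISTAR",
                                   rownames(d$exprs), n_perm = 400,
                                   seed = 9)
  expect_true(res$is_dc[res$gene == "DCGENE"])
  expect_true(res$is_dc[res$gene == "PARTNER"])
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  d <- .dc_expr(0.5, 0.5, n = 10)
  a <- differential_coexpression(d$exprs, d$meta, "liver", 1, "GK",
                                 "WISTAR", rownames(d$exprs),
                                 n_perm = 100, seed = 11)
  b <- differential_coexpression(d$exprs, d$meta, "liver", 1, "GK",
                                 "WISTAR", rownames(d$exprs),
                                 n_perm = 100, seed = 11)
  expect_equal(a, b)
})

test_that("degenerate DC inputs are handled: singleton sets and constants", {
  d <- .dc_expr(0.5, 0.5, n = 10)
  single <- differential_coexpression(d$exprs, d$meta, "liver", 1, "GK",
                                      "WISTAR", "DCGENE", n_perm = 50,
                                      seed = 1)
  expect_equal(nrow(single), 0)

  d$exprs["BG1", ] <- 7
  expect_warning(
    res <- differential_coexpression(d$exprs, d$meta, "liver", 1, "GK",
                                     "WISTAR", rownames(d$exprs),
                                     n_perm = 50, seed = 1),
    "constant")
  expect_false("BG1" %in% res$gene)
})

test_that("time points and tissues combine with union semantics", {
  de <- data.frame(
    gene = c("A", "A", "B"), tissue = c("liver", "liver", "muscle"),
    time = c(1, 3, 2), p_value = 0.001, fold_change = 3,
    is_de = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE
  )
  dc <- data.frame(
    gene = c("B", "C"), tissue = c("muscle", "adipose"), time = c(4, 1),
    dc_statistic = 1, p_value = 0.001, adjusted_p = 0.01,
    is_dc = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  comb <- combine_timepoints(de, dc)
  expect_true(comb$is_de[comb$gene == "A"])         # DE at one time point
  expect_equal(comb$de_tissues[comb$gene == "A"], "liver")
  expect_false(comb$is_de[comb$gene == "B"])
  expect_true(comb$is_dc[comb$gene == "B"])
  expect_true(comb$is_differential[comb$gene == "B"])
  expect_false(comb$is_differential[comb$gene == "C"])  # never flagged
})
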