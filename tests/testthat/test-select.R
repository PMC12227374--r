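test_that("Holm within gene matches hand and brute-force oracles", {
  expect_equal(holm_within_gene(0.03), 0.03)
  expect_equal(holm_within_gene(c(0.01, 0.04)), c(0.02, 0.04))
  # missing comparisons count as 1 before correction
  expect_equal(holm_within_gene(c(0.02, NA)), c(0.04, 1))
  expect_error(holm_within_gene(c(0.5, 1.01)), "\\[0, 1\\]")
  for (s in 1:40) {
    set.seed(s)
    p <- runif(sample(2:8, 1))
    expect_equal(holm_within_gene(p), oracle_holm(p), tolerance = 1e-12)
  }
})

test_that("Holm output dominates raw p and is monotone in order statistics", {
  set.seed(77)
  for (i in 1:20) {
    p <- runif(6)
    h <- holm_within_gene(p)
    expect_true(all(h >= p))
    expect_equal(order(h[order(p)]), 1:6)  # sorted input stays sorted
  }
})

test_that("row-wise Holm equals the per-row oracle including missing", {
  set.seed(5)
  p <- matrix(runif(150), 50, 3)
  p[sample(150, 10)] <- NA
  grid <- comparison_grid(p, comparisons = c("a", "b", "c"))
  sel <- suppressWarnings(select_shared(grid))
  manual <- t(apply(p, 1, function(r) { r[is.na(r)] <- 1; oracle_holm(r) }))
  dimnames(manual) <- dimnames(sel$holm)
  expect_equal(sel$holm, manual, tolerance = 1e-12)
})

test_that("total null: R can be 0 and every selection is empty", {
  p <- matrix(1, 20, 3, dimnames = list(sprintf("g%02d", 1:20), NULL))
  grid <- comparison_grid(p, comparisons = c("a", "b", "c"))
  expect_warning(sel <- select_shared(grid), "fdr_level \\* R is 0")
  expect_equal(sel$R, 0)
  expect_true(all(lengths(sel$per_comparison) == 0))
  expect_length(sel$intersection, 0)
})

test_that("planted signal genes land in the intersection", {
  set.seed(101)
  G <- 1000; C <- 5
  p <- matrix(runif(G * C), G, C,
              dimnames = list(sprintf("g%04d", 1:G),
                              paste0("c", 1:C)))
  planted <- sample(G, 10)
  p[planted, ] <- 1e-8
  grid <- comparison_grid(p)
  sel <- select_shared(grid)
  expect_true(all(rownames(p)[planted] %in% sel$intersection))
  # and the whole result agrees with the step-by-step oracle
  ora <- oracle_select_shared(p)
  expect_equal(sel$R, ora$R)
  for (j in 1:C)
    expect_equal(sel$per_comparison[[j]], rownames(p)[ora$sets[[j]]])
  expect_equal(sel$intersection, rownames(p)[ora$intersection])
})

test_that("selection equals the naive oracle on random grids", {
  for (s in 1:10) {
    set.seed(s)
    p <- matrix(runif(150), 50, 3,
                dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:3)))
    p[sample(150, 5)] <- NA
    p[sample(50, 3), ] <- rexp(9, 1000)  # a few strong genes
    p <- pmin(p, 1)
    sel <- suppressWarnings(select_shared(comparison_grid(p)))
    ora <- oracle_select_shared(p)
    for (j in 1:3)
      expect_equal(sel$per_comparison[[j]], rownames(p)[ora$sets[[j]]])
    expect_equal(sel$intersection, rownames(p)[ora$intersection])
    expect_true(all(sel$intersection %in% sel$per_comparison[[1]]))
  }
})

test_that("single comparison reduces to BH plus the scaled raw cut", {
  set.seed(303)
  p <- matrix(runif(200), 200, 1,
              dimnames = list(sprintf("g%03d", 1:200), "only"))
  p[1:8, ] <- 1e-7
  sel <- select_shared(comparison_grid(p), fdr_level = 0.1)
  fdr <- oracle_bh(p[, 1])
  R <- mean(fdr < 0.1)
  direct <- rownames(p)[fdr < 0.1 & p[, 1] < 0.1 * R]
  expect_equal(sel$per_comparison[[1]], direct)
  expect_equal(sel$intersection, direct)
})

test_that("null grids select at most an FDR-consistent fraction", {
  set.seed(42)
  fracs <- replicate(200, {
    p <- matrix(runif(100 * 3), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:3)))
    sel <- suppressWarnings(select_shared(comparison_grid(p)))
    max(lengths(sel$per_comparison)) / 100
  })
  mc_se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.1 + 3 * mc_se)
})

test_that("heatmap filter applies the inclusive bound in every tissue", {
  p <- matrix(1e-6, 4, 2,
              dimnames = list(paste0("g", 1:4), c("a:IP>input", "b:IP>input")))
  lfc <- rbind(c(1.2, 1.2),    # exactly on the inclusive bound: retained
               c(2.0, 0.9),    # fails one tissue
               c(1.5, 3.0),    # clear pass
               c(1.19, 2.0))   # just below in one tissue
  dimnames(lfc) <- dimnames(p)
  grid <- comparison_grid(p, lfc)
  sel <- select_shared(grid)
  expect_setequal(sel$intersection, paste0("g", 1:4))
  got <- heatmap_filter(sel, grid)
  expect_setequal(got, c("g1", "g3"))
  # empty input set stays empty
  sel0 <- sel; sel0$intersection <- character()
  expect_length(heatmap_filter(sel0, grid), 0)
})

test_that("prescreen intersects the two independent selections per tissue", {
  g <- sprintf("g%02d", 1:60)
  mk <- function(hits, comparisons) {
    p <- matrix(runif(60 * length(comparisons), 0.2, 1), 60,
                length(comparisons), dimnames = list(g, comparisons))
    for (j in seq_along(comparisons)) p[hits[[j]], j] <- 1e-9
    comparison_grid(p)
  }
  set.seed(9)
  # liver candidates: genes 1-5 pass IP>input, genes 3-8 pass IP>control
  gi <- mk(list(1:5, 40:45), c("liver:IP>input", "heart:IP>input"))
  gc <- mk(list(3:8, 40:45), c("liver:IP>control", "heart:IP>control"))
  pre <- prescreen_unique(gi, gc)
  expect_setequal(pre$candidates$liver, g[3:5])
  expect_setequal(pre$candidates$heart, g[40:45])
  expect_equal(pre$union_size, length(unique(c(g[3:5], g[40:45]))))
})

test_that("dominance screen keeps planted winners and honours replicate rule", {
  set.seed(21)
  sim <- simulate_counts(sim_design(
    n_genes = 500, tissues = c("brain", "liver", "wholefish"),
    n_replicates = 3, frac_enriched = 0, n_unique = 6, lfc_unique = 3,
    seed = 77))
  counts <- sim$counts; samples <- sim$samples
  sf <- estimate_size_factors(counts)
  g_pw <- ip_pairwise_grid(counts, samples, control = "wholefish",
                           size_factors = sf)
  norm <- sweep(counts, 2, sf, "/")
  planted_brain <- sim$truth$gene_id[sim$truth$class == "unique:brain"]
  planted_liver <- sim$truth$gene_id[sim$truth$class == "unique:liver"]
  cand <- list(brain = c(planted_brain, sim$truth$gene_id[1:5]),
               liver = planted_liver)
  scr <- dominance_screen(cand, g_pw, norm, samples, control = "wholefish")
  expect_gte(mean(planted_brain %in% scr$unique$brain), 0.8)
  expect_gte(mean(planted_liver %in% scr$unique$liver), 0.8)
  # a symmetric null gene fails the omnibus-backed criteria
  nulls <- sim$truth$gene_id[sim$truth$class == "null"][1:5]
  expect_false(any(nulls %in% unlist(scr$unique)))

  # replicate-minimum rule: degrade one brain IP replicate of a kept gene
  kept <- scr$unique$brain[1]
  liver_max <- max(norm[kept, samples$tissue == "liver" &
                          samples$fraction == "IP"])
  norm2 <- norm
  norm2[kept, which(samples$tissue == "brain" &
                      samples$fraction == "IP")[1]] <- liver_max * 0.9
  scr2 <- dominance_screen(cand, g_pw, norm2, samples,
                           control = "wholefish")
  expect_false(kept %in% scr2$unique$brain)
})

test_that("dominance screen is invariant to relabeling non-winning tissues", {
  set.seed(31)
  sim <- simulate_counts(sim_design(
    n_genes = 300, tissues = c("brain", "liver", "skin", "wholefish"),
    n_replicates = 3, frac_enriched = 0, n_unique = 4, lfc_unique = 3,
    seed = 55))
  sf <- estimate_size_factors(sim$counts)
  norm <- sweep(sim$counts, 2, sf, "/")
  g_pw <- ip_pairwise_grid(sim$counts, sim$samples, control = "wholefish",
                           size_factors = sf)
  planted <- sim$truth$gene_id[sim$truth$class == "unique:brain"]
  cand <- list(brain = planted)
  scr1 <- dominance_screen(cand, g_pw, norm, sim$samples,
                           control = "wholefish")
  # relabel: swap liver and skin everywhere
  samples2 <- sim$samples
  samples2$tissue <- c(liver = "skin", skin = "liver",
                       brain = "brain", wholefish = "wholefish")[samples2$tissue]
  g_pw2 <- ip_pairwise_grid(sim$counts, samples2, control = "wholefish",
                            size_factors = sf)
  scr2 <- dominance_screen(cand, g_pw2, norm, samples2,
                           control = "wholefish")
  expect_setequal(scr1$unique$brain, scr2$unique$brain)
})

test_that("fold filters: boundaries, ties, and a hand-worked filter-3 case", {
  ip <- rbind(g1 = c(a = 14, b = 10, c = 1),
              g2 = c(a = 20, b = 10, c = 1),
              g3 = c(a = 20, b = 20, c = 1),
              g4 = c(a = 40, b = 16, c = 1))
  input <- rbind(g1 = c(a = 10, b = 1, c = 1),
                 g2 = c(a = 5, b = 1, c = 1),
                 g3 = c(a = 5, b = 1, c = 1),
                 g4 = c(a = 10, b = 1, c = 10))
  means <- list(ip = ip, input = input)
  screen <- list(a = c("g1", "g2", "g3", "g4"))
  got <- fold_filters(screen, means)
  d <- got$diagnostics
  # g1: IP/input = 1.4 < 1.5 -> removed by filter (1)
  expect_false(d$pass_input_fold[d$gene_id == "g1"])
  # g2: IP exactly 2x next-highest -> retained by the inclusive filter (2)
  expect_true(d$pass_next_fold[d$gene_id == "g2"])
  expect_true("g2" %in% got$unique$a)
  # g3: exact IP tie with tissue b -> assigned to neither
  expect_true(d$tied[d$gene_id == "g3"])
  expect_false("g3" %in% got$unique$a)
  # g4 passes (1) 40/10=4 and (2) 40/16=2.5, but fails (3):
  # IP difference 40-16=24 < 2 * input difference 2*(10-1)=18 ... 24>=18 passes;
  # rebuild with input difference 15 so 2*15=30 > 24 fails
  input2 <- input; input2["g4", "a"] <- 16
  got2 <- fold_filters(screen, list(ip = ip, input = input2))
  expect_false(got2$diagnostics$pass_diff[got2$diagnostics$gene_id == "g4"])
  expect_false("g4" %in% got2$unique$a)
  expect_true("g4" %in% got$unique$a)
})

test_that("fold filters work on the log2 scale too", {
  ip <- rbind(g1 = c(a = 2^6, b = 2^3, c = 1))
  input <- rbind(g1 = c(a = 2^4, b = 2^2, c = 1))
  means <- list(ip = ip, input = input)
  # log2 scale: lfc vs input = 2 >= 1.5; vs next tissue = 3 >= 2;
  # diff-of-diffs: 3 >= 2 * (log2 in_a - log2 in_b ~ 2)? 3 < 4 -> fails (3)
  got <- fold_filters(list(a = "g1"), means, scale = "log2")
  d <- got$diagnostics
  expect_true(d$pass_input_fold && d$pass_next_fold)
  expect_false(d$pass_diff)
})
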