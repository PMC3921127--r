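# Jaccard machinery, Hungarian matching, common modules

test_that("jaccard index basics", {
  expect_equal(jaccard(1:5, 1:5), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(1:6, c(1:4, 7)), 4 / 7)
  expect_equal(jaccard(character(0), character(0)), 0)
  # symmetry on random sets
  set.seed(3)
  for (i in 1:10) {
    a <- sample(letters, 8); b <- sample(letters, 8)
    expect_equal(jaccard(a, b), jaccard(b, a))
  }
})

test_that("projection intersects modules with the universe", {
  ms <- module_set(list(m1 = as.character(1:6), m2 = as.character(7:9)))
  expect_identical(project_modules(ms, as.character(1:20))$modules,
                   ms$modules)
  p <- project_modules(ms, as.character(setdiff(1:8, 6)))
  expect_identical(p$modules$m1, as.character(1:5))
  expect_identical(p$modules$m2, as.character(7:8))
  expect_length(project_modules(ms, "zz")$modules$m1, 0L)
})

test_that("reproducibility scores project onto the shared universe", {
  ref <- module_set(list(r1 = as.character(1:6)))
  val <- module_set(list(v1 = as.character(c(1:4, 7))))
  # shared universe {1..8}: r1 projects to {1..6}, v1 stays {1,2,3,4,7}
  out <- reproducibility_scores(ref, val,
                                ref_universe = as.character(1:10),
                                val_universe = as.character(1:8),
                                min_size = 5L)
  expect_equal(unname(out$scores["r1"]), 4 / 7)

  # identical sets on one universe: all scores 1
  ms <- module_set(list(a = letters[1:7], b = letters[10:17]))
  out2 <- reproducibility_scores(ms, ms, letters, letters)
  expect_true(all(out2$scores == 1))
  expect_equal(out2$mean, 1)

  # a size-10 module split into two size-5 halves scores 0.5
  ref3 <- module_set(list(r = as.character(1:10)))
  val3 <- module_set(list(v1 = as.character(1:5), v2 = as.character(6:10)))
  out3 <- reproducibility_scores(ref3, val3, as.character(1:10),
                                 as.character(1:10))
  expect_equal(unname(out3$scores), 0.5)

  expect_error(
    reproducibility_scores(module_set(list(tiny = letters[1:3])), val3,
                           letters, letters),
    "size filter")
})

test_that("conservation scores use the shared universe without projection", {
  ref <- module_set(list(a = letters[1:8], b = letters[10:16]))
  expect_true(all(conservation_scores(ref, ref)$scores == 1))
  disj <- module_set(list(z = LETTERS[1:8]))
  expect_true(all(conservation_scores(ref, disj)$scores == 0))
  # strict filter: size 6 is eligible at min_size 5, size 5 is not
  small <- module_set(list(s5 = letters[1:5], s6 = letters[10:15]))
  out <- conservation_scores(small, ref, min_size = 5L)
  expect_identical(names(out$scores), "s6")
})

test_that("reproducibility is invariant to module order", {
  set.seed(21)
  mods <- split(sample(as.character(1:60)), rep(1:5, each = 12))
  names(mods) <- paste0("m", 1:5)
  val <- split(sample(as.character(1:60), 40), rep(1:4, each = 10))
  names(val) <- paste0("v", 1:4)
  u <- as.character(1:60)
  s1 <- reproducibility_scores(module_set(mods), module_set(val), u, u)
  s2 <- reproducibility_scores(module_set(rev(mods)),
                               module_set(rev(val)), u, u)
  expect_equal(s1$scores[names(mods)], s2$scores[names(mods)])
})

test_that("Hungarian matching is optimal against brute force", {
  expect_equal(match_modules(diag(3))$pairs$col, 1:3)

  S <- matrix(c(0.9, 0.8, 0.6, 0.1), 2, 2)  # [[0.9,0.6],[0.8,0.1]]
  m <- match_modules(S)
  expect_equal(m$total, 1.4)
  expect_equal(m$pairs$col[m$pairs$row == 1], 2)
  expect_equal(m$pairs$col[m$pairs$row == 2], 1)

  set.seed(42)
  for (i in 1:25) {
    nr <- sample(2:5, 1); nc <- sample(nr:6, 1)
    S <- matrix(runif(nr * nc), nr, nc)
    got <- match_modules(S)
    expect_equal(got$total, brute_force_assignment(S)$total,
                 tolerance = 1e-9)
    # one-to-one
    expect_equal(anyDuplicated(got$pairs$col), 0L)
  }
})

test_that("rectangular matching reports unmatched modules", {
  S <- matrix(runif(6), 3, 2,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:2)))
  m <- match_modules(S)
  expect_equal(nrow(m$pairs), 2L)
  expect_length(m$unmatched_rows, 1L)
  expect_length(m$unmatched_cols, 0L)
})

test_that("Hungarian total is at least any greedy matching total", {
  greedy_total <- function(S) {
    tot <- 0
    while (nrow(S) > 0 && ncol(S) > 0 && any(S > -Inf)) {
      ij <- which(S == max(S), arr.ind = TRUE)[1, ]
      tot <- tot + S[ij[1], ij[2]]
      S <- S[-ij[1], -ij[2], drop = FALSE]
    }
    tot
  }
  set.seed(13)
  for (i in 1:15) {
    S <- matrix(runif(25), 5, 5)
    expect_gte(match_modules(S)$total + 1e-12, greedy_total(S))
  }
})

test_that("common modules intersect matched pairs with a size floor", {
  ms1 <- module_set(list(p = as.character(1:8), q = letters[1:6]))
  ms2 <- module_set(list(u = as.character(3:10), v = letters[1:4]))
  pairs <- data.frame(row = c("p", "q"), col = c("u", "v"),
                      stringsAsFactors = FALSE)
  cm <- common_modules(ms1, ms2, pairs, min_size = 5L)
  expect_equal(length(cm), 1L)                 # {3..8} kept, size-4 dropped
  expect_setequal(cm$modules[[1]], as.character(3:8))
  # identical pair: the module itself
  cm2 <- common_modules(ms1, ms1, data.frame(row = "p", col = "p"),
                        min_size = 5L)
  expect_setequal(cm2$modules[[1]], as.character(1:8))
})
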