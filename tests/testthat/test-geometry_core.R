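# geometry_core: z-normalization, RDM construction, vectorization,
# comparison, Fisher transform, and the TSV interfaces.

test_that("znormalize_pattern matches its contract and the moment oracle", {
  expect_equal(znormalize_pattern(c(1, 2, 3)), c(-1, 0, 1))
  z <- znormalize_pattern(c(-1, 0, 1))
  expect_equal(znormalize_pattern(z), z)  # idempotent on z-scored input
  set.seed(11)
  x <- rnorm(50, mean = 3, sd = 7)
  z <- znormalize_pattern(x)
  mo <- oracle_moments(z)
  expect_equal(mo$mean, 0, tolerance = 1e-12)
  expect_equal(mo$sd, 1, tolerance = 1e-12)
  expect_error(znormalize_pattern(rep(2, 5), label = "faces"),
               "zero-variance.*faces")
  expect_error(znormalize_pattern(3), "at least 2")
})

test_that("build_rdm agrees with brute-force double loops (K <= 10)", {
  expect_equal(oracle_euclidean(c(0, 0), c(3, 4)), 5)  # 3-4-5 sanity
  for (seed in 1:5) {
    rm <- rand_response_matrix(k = sample(4:10, 1), v = 6, seed = seed)
    rz <- t(apply(rm, 1, znormalize_pattern))
    expect_equal(unclass(build_rdm(rm, "euclidean_z")),
                 oracle_rdm(rz, "euclidean"),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(unclass(build_rdm(rm, "correlation_distance")),
                 oracle_rdm(unclass(rm), "correlation"),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(unclass(build_rdm(rm, "euclidean")),
                 oracle_rdm(unclass(rm), "euclidean"),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("RDM invariants hold on every construction", {
  for (seed in 1:10) {
    rdm <- build_rdm(rand_response_matrix(k = 6, v = 5, seed = seed),
                     sample(c("euclidean_z", "correlation_distance"), 1))
    expect_silent(validate_rdm(rdm))
  }
  m <- rand_response_matrix(4, 5, seed = 1)
  m[2, ] <- m[1, ]  # identical rows -> zero distance
  expect_equal(build_rdm(response_matrix(m), "euclidean")[1, 2], 0)
  m[3, ] <- 5  # constant row
  expect_error(build_rdm(response_matrix(m), "correlation_distance"),
               "zero-variance.*c3")
})

test_that("vectorize_rdm follows the row-major convention and round-trips", {
  rdm3 <- rdm_from_vector(c(10, 20, 30), c("a", "b", "c"))
  expect_equal(rdm3["a", "b"], 10)
  expect_equal(rdm3["a", "c"], 20)
  expect_equal(rdm3["b", "c"], 30)
  expect_equal(unname(vectorize_rdm(rdm3)), c(10, 20, 30))
  expect_named(vectorize_rdm(rdm3), c("a|b", "a|c", "b|c"))
  for (k in c(8, 17)) {
    rdm <- build_rdm(rand_response_matrix(k, 6, seed = k), "euclidean_z")
    v <- vectorize_rdm(rdm)
    expect_length(v, k * (k - 1) / 2)
    back <- rdm_from_vector(v, rownames(rdm))
    expect_equal(unclass(back), unclass(rdm), ignore_attr = TRUE)
  }
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3)
  expect_error(vectorize_rdm(new_rdm_for_test(bad)), "symmetric|diagonal")
})

test_that("compare_rdms matches the mid-rank oracle, incl. ties", {
  set.seed(21)
  a <- rnorm(20)
  expect_equal(compare_rdms(a, a), 1)
  expect_equal(compare_rdms(a, a, "pearson"), 1)
  b <- -a  # rank reversal, no ties
  expect_equal(compare_rdms(a, b), -1)
  for (seed in 1:8) {
    set.seed(seed)
    x <- sample(1:5, 12, replace = TRUE) + 0  # heavy ties
    y <- sample(1:4, 12, replace = TRUE) + rnorm(12, sd = 0.01)
    expect_equal(compare_rdms(x, y, "spearman"), oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(compare_rdms(x, y, "pearson"), oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
  expect_error(compare_rdms(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(compare_rdms(1:4, 1:5), "equal length")
})

test_that("compare_rdms is symmetric and invariant to common reordering", {
  set.seed(3)
  a <- rnorm(28); b <- rnorm(28)
  for (m in c("spearman", "pearson")) {
    expect_equal(compare_rdms(a, b, m), compare_rdms(b, a, m))
    perm <- sample(28)
    expect_equal(compare_rdms(a[perm], b[perm], m), compare_rdms(a, b, m),
                 tolerance = 1e-12)
  }
})

test_that("fisher_z is arctanh with odd symmetry and boundary clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  for (r in c(0.1, 0.35, 0.99)) expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clamp")
  expect_equal(z1, atanh(1 - 1e-12))
  expect_warning(zm <- fisher_z(-1), "clamp")
  expect_equal(zm, -atanh(1 - 1e-12))
})

test_that("rank equivalence: euclidean_z and correlation distance agree in rank", {
  # squared euclidean_z distance = 2 (V-1) (1 - r) for sample-sd z-scoring
  rm <- rand_response_matrix(k = 6, v = 9, seed = 5)
  ev <- vectorize_rdm(build_rdm(rm, "euclidean_z"))
  cv <- vectorize_rdm(build_rdm(rm, "correlation_distance"))
  expect_equal(ev^2, 2 * (ncol(rm) - 1) * cv, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(compare_rdms(ev, cv, "spearman"), 1)
  # pearson between the two vectorizations is generally NOT 1
  expect_lt(compare_rdms(ev, cv, "pearson"), 1)
})

test_that("response matrices, RDMs and vectors round-trip through TSV", {
  dir <- withr::local_tempdir()
  rm <- rand_response_matrix(5, 7, seed = 9)
  f <- file.path(dir, "rm.tsv")
  write_response_matrix(rm, f)
  expect_equal(unclass(read_response_matrix(f)), unclass(rm),
               ignore_attr = TRUE, tolerance = 1e-12)
  rdm <- build_rdm(rm, "euclidean_z")
  f2 <- file.path(dir, "rdm.tsv")
  write_rdm(rdm, f2)
  expect_equal(unclass(read_rdm(f2)), unclass(rdm), ignore_attr = TRUE,
               tolerance = 1e-10)
  v <- vectorize_rdm(rdm)
  f3 <- file.path(dir, "v.tsv")
  write_dissimilarity_vector(v, f3)
  expect_equal(read_dissimilarity_vector(f3), v, tolerance = 1e-12)
})

test_that("response_matrix rejects invalid inputs", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "a"), NULL))
  expect_error(response_matrix(m), "unique")
  expect_error(response_matrix(matrix(rnorm(4), 2, 2,
                                      dimnames = list(c("a", "b"), NULL))),
               "at least 3")
  m2 <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2, dimnames = list(letters[1:3], NULL))
  expect_error(response_matrix(m2), "missing")
})
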