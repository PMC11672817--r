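test_that("pedigree files parse, renumber and round-trip labels", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 1 2", "1 0 0", "2 0 0"), path) # progeny listed first
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3L)
  expect_equal(sum(ped$founder), 2L)
  # topological order: parents precede progeny
  i3 <- which(ped$label == "3")
  expect_true(all(ped$id[ped$label %in% c("1", "2")] < ped$id[i3]))
  expect_equal(ped$sire[i3], pedigree_id(ped, "1"))
  expect_equal(ped$dam[i3], pedigree_id(ped, "2"))
  # labels map back losslessly
  expect_equal(ped$label[pedigree_id(ped, c("2", "3", "1"))], c("2", "3", "1"))

  # comma-delimited with header
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "a,0,0", "b,0,0", "c,a,b"), path2)
  ped2 <- read_pedigree(path2)
  expect_equal(sort(ped2$label), c("a", "b", "c"))
  expect_equal(sum(ped2$founder), 2L)
})

test_that("malformed pedigrees are rejected", {
  expect_error(as_pedigree(data.frame(a = c(1, 1), s = c(0, 0), d = c(0, 0))),
               "duplicate")
  expect_error(as_pedigree(data.frame(a = 3, s = 3, d = 2)), "cycle")
  expect_error(as_pedigree(data.frame(a = c(1, 2), s = c(2, 1), d = c(0, 0))),
               "cycle")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0", "2 0"), path)
  expect_error(read_pedigree(path), "3 columns")
})

test_that("inbreeding matches classic values and the tabular oracle", {
  # founders only
  ped <- as_pedigree(data.frame(a = 1:4, s = 0, d = 0))
  expect_equal(unname(inbreeding(ped)), rep(0, 4))

  # progeny of full sibs from unrelated parents: F = 0.25
  ped <- as_pedigree(data.frame(a = 1:5, s = c(0, 0, 1, 1, 3),
                                d = c(0, 0, 2, 2, 4)))
  expect_equal(unname(inbreeding(ped))[5], 0.25)
  expect_equal(mean_inbreeding(ped, "5"), 0.25)
  expect_equal(mean_inbreeding(ped, c("1", "2")), 0)

  # random pedigree vs dense tabular oracle, F = diag(A) - 1
  set.seed(101)
  ped <- random_pedigree(50)
  A <- oracle_A(ped$sire, ped$dam)
  expect_equal(unname(inbreeding(ped)), diag(A) - 1, tolerance = 1e-12)
})

test_that("mean_inbreeding validates its subset", {
  ped <- as_pedigree(data.frame(a = 1:3, s = c(0, 0, 1), d = c(0, 0, 2)))
  expect_error(mean_inbreeding(ped, character(0)), "empty")
  expect_error(mean_inbreeding(ped, "nope"), "not in pedigree")
})

test_that("dense A follows the tabular recursions and is PSD", {
  # trio: two unrelated parents and a progeny
  ped <- as_pedigree(data.frame(a = 1:3, s = c(0, 0, 1), d = c(0, 0, 2)))
  A <- build_A(ped)
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "2"], 0.5)
  expect_equal(A["1", "2"], 0)

  # single founder
  ped1 <- as_pedigree(data.frame(a = 1, s = 0, d = 0))
  expect_equal(unname(build_A(ped1)), matrix(1, 1, 1))

  # random pedigree: equals oracle, symmetric, PSD
  set.seed(7)
  ped <- random_pedigree(20)
  A <- build_A(ped)
  expect_equal(unname(A), oracle_A(ped$sire, ped$dam), tolerance = 1e-12)
  expect_equal(A, t(A))
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # size guard
  expect_error(build_A(ped, max_n = 10), "build_A_inverse")
})

test_that("sparse A-inverse inverts A on random pedigrees", {
  ped <- as_pedigree(data.frame(a = 1:3, s = 0, d = 0))
  expect_equal(as.matrix(build_A_inverse(ped)), diag(3), ignore_attr = TRUE)

  set.seed(42)
  for (n in c(30, 50)) {
    ped <- random_pedigree(n)
    A <- build_A(ped)
    Ainv <- as.matrix(build_A_inverse(ped))
    expect_lt(max(abs(A %*% Ainv - diag(n))), 1e-8)
  }
})

test_that("the inbreeding adjustment in A-inverse matters", {
  # full-sib mating chain deep enough that inbred animals have progeny
  # (the Mendelian-sampling shrinkage only enters through the parents' F)
  ped <- as_pedigree(data.frame(a = 1:8, s = c(0, 0, 1, 1, 3, 3, 5, 5),
                                d = c(0, 0, 2, 2, 4, 4, 6, 6)))
  f <- inbreeding(ped)
  expect_equal(max(f), 0.375) # progeny of two F = 0.25 full sibs
  A <- build_A(ped)
  good <- as.matrix(build_A_inverse(ped, f))
  expect_lt(max(abs(A %*% good - diag(8))), 1e-8)
  # dropping the adjustment (F = 0) breaks the inverse
  bad <- as.matrix(build_A_inverse(ped, f = rep(0, 8)))
  expect_gt(max(abs(A %*% bad - diag(8))), 1e-3)
})

test_that("A algebra holds across many random pedigrees", {
  set.seed(2024)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    ped <- random_pedigree(n)
    A <- build_A(ped)
    expect_equal(unname(inbreeding(ped)), unname(diag(A) - 1),
                 tolerance = 1e-10)
    expect_lt(max(abs(A %*% as.matrix(build_A_inverse(ped)) - diag(n))),
              1e-8)
  }
})
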