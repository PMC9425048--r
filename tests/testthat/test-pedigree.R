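random_pedigree <- function(n, seed) {
  # founders first, then animals whose parents are drawn from earlier animals
  set.seed(seed)
  nf <- max(4L, round(n * 0.2))
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("X%03d", seq_len(n))
  for (i in (nf + 1L):n) {
    pool <- ids[seq_len(i - 1L)]
    sire[i] <- sample(pool, 1)
    dam[i] <- sample(setdiff(pool, sire[i]), 1)
    if (runif(1) < 0.1) dam[i] <- NA  # some unknown dams
  }
  data.frame(animal = ids, sire = sire, dam = dam)
}

test_that("read_pedigree sorts parents before offspring regardless of input order", {
  ped <- read_pedigree(data.frame(animal = c("B", "A"),
                                  sire = c("A", "0"), dam = c("", "0")))
  expect_equal(ped$animal, c("A", "B"))
  expect_true(is.na(ped$sire[1]))
  # already ordered input stays ordered
  ped2 <- read_pedigree(data.frame(animal = c("A", "B"),
                                   sire = c(NA, "A"), dam = c(NA, NA)))
  expect_equal(ped2$animal, c("A", "B"))
  # shuffled larger pedigree: every parent precedes its offspring
  raw <- random_pedigree(60, seed = 1)
  shuf <- raw[sample(nrow(raw)), ]
  srt <- read_pedigree(shuf)
  pos <- seq_len(nrow(srt)); names(pos) <- srt$animal
  ok <- mapply(function(a, p) is.na(p) || pos[p] < pos[a], srt$animal, srt$sire) &
        mapply(function(a, p) is.na(p) || pos[p] < pos[a], srt$animal, srt$dam)
  expect_true(all(ok))
})

test_that("pedigree cycles and duplicates are hard errors", {
  expect_error(read_pedigree(data.frame(animal = c("A", "B"),
                                        sire = c("B", "A"), dam = c("0", "0"))),
               "cycle")
  expect_error(read_pedigree(data.frame(animal = c("A", "A"),
                                        sire = c("0", "0"), dam = c("0", "0"))),
               "duplicate")
})

test_that("build_A reproduces textbook relationships", {
  # two unrelated founders
  A <- build_A(data.frame(animal = c("P1", "P2"), sire = c("0", "0"),
                          dam = c("0", "0")))
  expect_equal(unname(A), diag(2))
  # parent-offspring
  A <- build_A(data.frame(animal = c("P1", "P2", "O"),
                          sire = c("0", "0", "P1"), dam = c("0", "0", "P2")))
  expect_equal(A["P1", "O"], 0.5)
  expect_equal(A["O", "O"], 1)
  # full sibs related 0.5; their offspring (full-sib mating) inbred F = 0.25
  ped <- data.frame(animal = c("S", "D", "F1", "F2", "O"),
                    sire = c("0", "0", "S", "S", "F1"),
                    dam  = c("0", "0", "D", "D", "F2"))
  A <- build_A(ped)
  expect_equal(A["F1", "F2"], 0.5)
  expect_equal(A["O", "O"], 1.25)
  expect_equal(inbreeding_coef(ped)[["O"]], 0.25)
  expect_equal(unname(inbreeding_coef(ped)[c("S", "D", "F1", "F2")]),
               rep(0, 4))
})

test_that("A is symmetric PSD and invariant to input row order", {
  for (seed in 1:3) {
    raw <- random_pedigree(80, seed = seed)
    A <- build_A(raw)
    expect_equal(A, t(A))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_true(all(diag(A) >= 1 - 1e-12 & diag(A) <= 2 + 1e-12))
    # row-order invariance of pairwise relationship
    shuf <- raw[sample(nrow(raw)), ]
    A2 <- build_A(shuf)
    expect_equal(A2[rownames(A), colnames(A)], A)
  }
})

test_that("build_A_inverse inverts build_A, including under inbreeding", {
  # founders only -> identity
  ped <- data.frame(animal = c("A", "B", "C"), sire = "0", dam = "0")
  expect_equal(as.matrix(build_A_inverse(ped)), diag(3),
               ignore_attr = TRUE)
  # trio matches dense inverse
  trio <- data.frame(animal = c("P1", "P2", "O"),
                     sire = c("0", "0", "P1"), dam = c("0", "0", "P2"))
  expect_equal(as.matrix(build_A_inverse(trio)), solve(build_A(trio)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # random pedigrees (with inbred matings) against dense inversion
  for (seed in 4:6) {
    ped <- random_pedigree(120, seed = seed)
    A <- build_A(ped)
    Ainv <- build_A_inverse(ped)
    prod <- as.matrix(A %*% Ainv)
    expect_lt(max(abs(prod - diag(nrow(A)))), 1e-8)
  }
})

test_that("A inverse matches dense inversion on a 500-animal pedigree", {
  ped <- random_pedigree(500, seed = 9)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)
  expect_lt(max(abs(as.matrix(A %*% Ainv) - diag(500))), 1e-8)
})
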