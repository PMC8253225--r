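test_that("founders are homozygous and complementary", {
  map <- generate_map(seed = 1)
  donor_loci <- c("C1M4", "C1M6", "C2M9", "C3M1", "C5M4", "C6M3", "C6M8")
  fd <- make_founders(map, donor_loci)
  expect_equal(sum(fd$elite) / 2, 93)
  expect_equal(sum(fd$donor) / 2, 7)
  expect_true(all(fd$elite[, 1] == fd$elite[, 2]))  # homozygous throughout
  expect_true(all(fd$donor[, 1] == fd$donor[, 2]))
  expect_true(all(fd$elite + fd$donor == 1))        # complementary per homolog
  expect_equal(unname(which(fd$donor[, 1] == 1)),
               sort(match(donor_loci, map$marker)))
  expect_error(make_founders(map, "C99M1"), "unknown marker")
})

test_that("empty donor set makes the elite the ideal genotype", {
  map <- toy_map()
  fd <- make_founders(map, character(0))
  expect_equal(fd$elite, ideal_genotype(map), ignore_attr = TRUE)
  expect_equal(sum(fd$donor), 0)
})

test_that("reproduction of homozygous parents yields identical heterozygous F1", {
  map <- toy_map()
  fd <- toy_founders()
  pop <- reproduce(fd$elite, fd$donor, map, K = 25, seed = 1)
  expect_equal(dim(pop$geno), c(10, 2, 25))
  expect_true(all(pop$geno %in% c(0L, 1L)))
  # every progeny identical: one gamete type per homozygous parent
  expect_true(all(apply(pop$geno, 3, identical, pop$geno[, , 1])))
  # heterozygous at every locus where parents differ (here: all loci)
  expect_true(all(pop$geno[, 1, 1] + pop$geno[, 2, 1] == 1))
  expect_false(is_ideal(pop))
  expect_error(reproduce(fd$elite, fd$donor, map, K = 0), "positive")
})

test_that("per-locus inheritance from a heterozygous parent is Mendelian", {
  m1 <- map_from_f(numeric(0))
  het <- matrix(c(1L, 0L), 1, 2)
  null <- matrix(0L, 1, 2)
  K <- 1e4
  pop <- reproduce(het, null, m1, K = K, seed = 7)
  n1 <- sum(pop$geno[1, 1, ])
  chisq <- (n1 - K / 2)^2 / (K / 4) * 2  # 2-cell goodness of fit
  expect_lt(chisq, qchisq(0.999, df = 1))
  # spec'd binomial window: 0.5 +/- 3 * sqrt(0.25 / K)
  expect_lt(abs(n1 / K - 0.5), 3 * sqrt(0.25 / K))
})

test_that("two-locus gamete frequencies follow the recombination fraction", {
  K <- 4e4
  for (f in c(0, 0.1, 0.5)) {
    m2 <- map_from_f(f)
    coupling <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # desirable alleles in cis
    null <- matrix(0L, 2, 2)
    pop <- reproduce(coupling, null, m2, K = K, seed = round(100 * f) + 1)
    gam <- pop$geno[, 1, ]  # the coupling parent's gametes
    type <- paste0(gam[1, ], gam[2, ])
    freq <- c(`11` = 0, `00` = 0, `10` = 0, `01` = 0)
    freq[names(table(type))] <- table(type) / K
    expected <- c((1 - f) / 2, (1 - f) / 2, f / 2, f / 2)
    tol <- 3 * sqrt(0.25 / K) + 1e-9
    expect_true(all(abs(freq - expected) < tol),
                label = paste("gamete frequencies at f =", f))
  }
})

test_that("with no recombination each gamete copies one parental homolog", {
  m <- map_from_f(c(0, 0, 0, 0.5, 0, 0, 0), chrom = rep(c("C1", "C2"),
                                                        each = 4))
  parent <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L,
                     0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), 8, 2)
  null <- matrix(0L, 8, 2)
  pop <- reproduce(parent, null, m, K = 50, seed = 9)
  for (k in 1:50) for (ch in c("C1", "C2")) {
    rows <- which(m$chrom == ch)
    g <- unname(pop$geno[rows, 1, k])
    expect_true(identical(g, unname(parent[rows, 1])) ||
                  identical(g, unname(parent[rows, 2])))
  }
})

test_that("ideal detection keys on the 2N allele sum", {
  map <- toy_map()
  geno <- array(0L, dim = c(10, 2, 3))
  geno[, , 2] <- 1L  # member 2 is ideal
  pop <- matiMDP:::new_population(geno, 1L)
  res <- is_ideal(pop)
  expect_true(res)
  expect_equal(attr(res, "index"), 2L)
  expect_equal(allele_counts(pop), c(0L, 20L, 0L))
})

test_that("genotype and population CSV writers round-trip", {
  map <- toy_map()
  fd <- toy_founders()
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(fd$donor, p1)
  expect_equal(read_genotype_csv(p1, map), fd$donor, ignore_attr = TRUE)
  pop <- reproduce(fd$elite, fd$donor, map, K = 4, seed = 2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, p2)
  d <- read.csv(p2)
  expect_equal(nrow(d), 4 * 10)
  expect_equal(unique(d$generation), 0)
  expect_equal(d$hom1[d$individual == 3], unname(pop$geno[, 1, 3]))
})
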