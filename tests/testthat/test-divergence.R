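test_that("p-distance uses pairwise deletion and matches hand counts", {
  # 10 columns, 1 mismatch, 2 gapped columns -> 1/8
  m <- aln_mat(x = "ACGTACGTAC", y = "ACGTACGTAG")
  m["x", 3] <- "-"; m["y", 7] <- "N"
  ds <- pDistance(m)
  expect_equal(distances(ds)["x", "y"], 1 / 8)
  # identical rows -> 0
  expect_equal(distances(pDistance(aln_mat(a = "ACGT", b = "ACGT")))["a", "b"], 0)
  # zero comparable sites is flagged
  expect_warning(pDistance(aln_mat(a = "AC--", b = "--GT")), "no comparable")
})

test_that("p-distance agrees with the reference distance implementation", {
  set.seed(201)
  for (i in 1:3) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 300, TRUE,
                         prob = c(.24, .24, .24, .24, .04)), 5, 300,
                  dimnames = list(paste0("t", 1:5), NULL))
    ours <- distances(pDistance(mat))
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(mat)),
                                   model = "raw", pairwise.deletion = TRUE))
    expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12)
  }
})

test_that("p-distance is invariant to row and column permutations", {
  set.seed(203)
  mat <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 100, TRUE), 4, 100,
                dimnames = list(letters[1:4], NULL))
  d0 <- distances(pDistance(mat))
  rp <- sample(4); cp <- sample(100)
  d1 <- distances(pDistance(mat[rp, ]))
  expect_equal(d1[rownames(d0), colnames(d0)], d0)
  d2 <- distances(pDistance(mat[, cp]))
  expect_equal(d2, d0)
})

test_that("group means are consistent with the pairwise values", {
  set.seed(205)
  mat <- matrix(sample(c("A", "C", "G", "T"), 6 * 200, TRUE), 6, 200,
                dimnames = list(LETTERS[1:6], NULL))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 3), LETTERS[1:6])
  ds <- pDistance(mat, groups = groups)
  d <- distances(ds)
  pairs <- d[upper.tri(d)]
  expect_equal(ds@overall, mean(pairs))
  # the overall mean is the weighted mean of within- and between-group values
  same <- outer(groups, groups, "==")[upper.tri(d)]
  expect_equal(ds@overall,
               (sum(pairs[same]) + sum(pairs[!same])) / length(pairs))
  expect_equal(ds@between, mean(pairs[!same]))
  g1 <- d[1:3, 1:3]
  expect_equal(unname(ds@within[["g1"]]), mean(g1[upper.tri(g1)]))
})

test_that("identity profile windows are reference anchored", {
  # identical pair: 100% everywhere
  ip <- identityProfile(c(r = "ACGTACGTACGT", o = "ACGTACGTACGT"), "r",
                        window = 4, step = 4)
  expect_true(all(ip$identity == 100))
  # a mismatch block inside one window drops it to (window-k)/window
  r <- strrep("A", 100); o <- paste0(strrep("A", 40), strrep("C", 10),
                                     strrep("A", 50))
  ip2 <- identityProfile(c(r = r, o = o), "r", window = 50, step = 50)
  expect_equal(ip2$identity, c(100 * 40 / 50, 100))
  # reference gap columns are collapsed before windowing
  m <- aln_mat(r = "AC-GT", o = "ACCGT")
  ip3 <- identityProfile(m, "r", window = 4, step = 4)
  expect_equal(ip3$identity, 100)  # the inserted column does not count
})

test_that("region variability counts substitutions and indel events as specified", {
  # direct formula: L = 100, NS = 3, ID = 1 -> 4.0%
  base <- strrep("A", 100)
  r1 <- base
  r2 <- base; substr(r2, 10, 10) <- "C"; substr(r2, 20, 20) <- "G"
  r3 <- base; substr(r3, 30, 30) <- "T"
  r2 <- paste0(substr(r2, 1, 50), "-----", substr(r2, 56, 100))
  rv <- regionVariability(c(a = r1, b = r2, c = r3))
  expect_equal(rv$L, 100L)
  expect_equal(rv$NS, 3L)
  expect_equal(rv$ID, 1L)
  expect_equal(rv$variation_percent, 4.0)
  expect_equal(rv$variable_sites, 3L)
  expect_equal(rv$PI_sites, 0L)
  # two taxa sharing a deletion at identical coordinates: one event
  m <- aln_mat(a = "AAAAAAAAAA", b = "AA-----AAA", c = "AA-----AAA",
               d = "AAAAAAAAAA")
  expect_equal(regionVariability(m)$ID, 1L)
  # same start, different length: two events
  m2 <- aln_mat(a = "AAAAAAAAAA", b = "AA-----AAA", c = "AA---AAAAA")
  expect_equal(regionVariability(m2)$ID, 2L)
  # marker mode always >= substitutions-only mode
  expect_gte(regionVariability(m)$variation_percent,
             regionVariability(m, countIndels = FALSE)$variation_percent)
  # a column with two states each in two taxa is parsimony informative
  m3 <- aln_mat(a = "AC", b = "AC", c = "GC", d = "GC")
  expect_equal(regionVariability(m3)$PI_sites, 1L)
  expect_error(regionVariability(matrix(character(), 2, 0)), "empty")
})

test_that("marker ranking sorts by variability and applies the thresholds", {
  st <- data.frame(name = c("r1", "r2", "r3", "r4"),
                   class = "noncoding", L = 100, NS = c(8, 3, 5, 5),
                   ID = 0, variable_sites = c(8, 3, 5, 5),
                   PI_sites = c(4, 1, 4, 2),
                   variation_percent = c(8, 3, 5, 5),
                   PI_percent = c(4, 1, 4, 2))
  rk <- rankMarkers(st, k = 3)
  expect_equal(rk$name, c("r1", "r3", "r4"))  # tie broken by PI%
  expect_equal(attr(rk, "n_variation_gt4"), 3L)
  expect_equal(attr(rk, "n_pi_gt3"), 2L)
  single <- rankMarkers(st[1, ], k = 20)
  expect_equal(single$rank, 1L)
})

test_that("planted hot regions outrank the rest", {
  cfg <- simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                          geneSet = "mini", inversions = list())
  hot <- c("trnD(GUC)-psbM", "rbcL-psaI", "psaC-ndhE")
  cfg <- plantMarkers(cfg, hot, fold = 8)
  sim <- simulatePlastomes(cfg, seed = 77)
  aln <- trueAlignment(sim)
  ref <- rownames(aln)[1]
  refcols <- which(aln[ref, ] != "-")
  rec <- leafRecords(sim)[[ref]]
  regs <- partitionRegions(rec, minLen = 150)
  nc <- regs[regs$class == "noncoding", ]
  st <- do.call(rbind, lapply(seq_len(nrow(nc)), function(i)
    regionVariability(aln[, refcols[nc$start[i]]:refcols[nc$end[i]]],
                      name = nc$name[i], class = "noncoding")))
  rk <- rankMarkers(st, k = 3)
  expect_setequal(rk$name, hot)
})

test_that("plantMarkers validates regions and fold = 0 freezes a region", {
  cfg <- simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                          geneSet = "mini", inversions = list(),
                          indelRate = 0, repeatBirthRate = 0)
  expect_error(plantMarkers(cfg, "no-such-region", 2), "unknown region")
  cfg0 <- plantMarkers(cfg, "trnD(GUC)-psbM", fold = 0)
  sim <- simulatePlastomes(cfg0, seed = 31)
  aln <- trueAlignment(sim)
  ref <- rownames(aln)[1]
  refcols <- which(aln[ref, ] != "-")
  rec <- leafRecords(sim)[[ref]]
  regs <- partitionRegions(rec, minLen = 1)
  r <- regs[regs$name == "trnD(GUC)-psbM", ]
  rv <- regionVariability(aln[, refcols[r$start]:refcols[r$end]])
  expect_equal(rv$variation_percent, 0)
})

test_that("OLS fit matches the closed-form normal equations", {
  # perfectly collinear points
  f <- fitLinear(1:5, 2 * (1:5) + 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 2)
  set.seed(211)
  x <- runif(10); y <- 1.5 * x + rnorm(10, sd = .1)
  f <- fitLinear(x, y)
  # normal-equation oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f$slope, beta[2], tolerance = 1e-10)
  # R^2 invariant to affine rescaling of x and y
  f2 <- fitLinear(3 * x + 7, -2 * y + 1)
  expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-12)
  expect_error(fitLinear(rep(1, 5), 1:5), "zero variance")
  expect_error(fitLinear(1:2, 1:2), "three")
})

test_that("subfamily profiles are substitutions-only and group-symmetric", {
  set.seed(213)
  reg <- matrix(sample(c("A", "C", "G", "T"), 3 * 250, TRUE), 3, 250,
                dimnames = list(c("x", "y", "z"), NULL))
  alns <- list(Pooideae = list(r1 = reg), Bambusoideae = list(r1 = reg))
  prof <- subfamilyProfiles(alns, minLen = 200)
  expect_equal(prof$Pooideae, prof$Bambusoideae)
  # a region absent from one group yields NA there
  alns$Pooideae$r2 <- reg
  prof2 <- subfamilyProfiles(alns, minLen = 200)
  expect_true(is.na(prof2$Bambusoideae[prof2$region == "r2"]))
  # indels are not scored in this mode
  reg2 <- reg; reg2[1, 1:10] <- "-"
  alns2 <- list(g = list(r = reg), g2 = list(r = reg2))
  expect_equal(prof2$Pooideae[1],
               regionVariability(reg, countIndels = FALSE)$variation_percent)
})
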