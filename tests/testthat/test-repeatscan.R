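test_that("dispersed finder agrees exactly with the quadratic oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    ch <- rand_chars(320)
    if (seed %% 2 == 0) {         # plant a duplication, eroded on odd seeds
      ch[201:240] <- ch[51:90]
      if (seed == 4) ch[210] <- setdiff(c("A","C","G","T"), ch[210])[1]
    }
    s <- paste(ch, collapse = "")
    got <- findDispersed(s)
    want <- oracle_dispersed(ch)
    expect_identical(motif_sig(got), motif_sig(want))
    if (seed %% 2 == 0) expect_gt(nrow(got), 0)
  }
  # below the length threshold nothing is returned
  expect_equal(nrow(findDispersed("ACGTACGT")), 0L)
})

test_that("palindromic finder agrees exactly with the quadratic oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    ch <- rand_chars(400)
    if (seed >= 3) {              # plant a hairpin: 30 bp arms, 100 bp gap
      ch[231:260] <- o_revcomp(ch[101:130])
    }
    s <- paste(ch, collapse = "")
    got <- findPalindromic(s)
    want <- oracle_palindromic(ch)
    expect_identical(motif_sig(got), motif_sig(want))
    if (seed >= 3) {
      # the planted arms lie inside a reported (maximally extended) motif
      hit <- got[got$start1 <= 101 & got$end1 >= 130 &
                   got$start2 <= 231 & got$end2 >= 260, ]
      expect_equal(nrow(hit), 1L)
      expect_gte(hit$identity, 0.9)
      # in exact mode the planted arms are recovered at identity 1 (the
      # window may extend by a base or two when flanks match by chance)
      ex <- findPalindromic(s, minIdentity = 1)
      expect_true(any(ex$start1 <= 101 & ex$end1 >= 130 & ex$identity == 1))
    }
  }
})

test_that("palindromic gap constraint is enforced", {
  set.seed(41)
  ch <- rand_chars(2000)
  ch[1501:1530] <- o_revcomp(ch[101:130])  # gap ~1370
  s <- paste(ch, collapse = "")
  hit <- findPalindromic(s, maxGap = 3000)
  expect_true(any(hit$start1 <= 101 & hit$end2 >= 1530))
  miss <- findPalindromic(s, maxGap = 1000)
  expect_false(any(miss$start1 <= 101 & miss$end2 >= 1530))
})

test_that("tandem finder matches the period-scan oracle and the unit threshold", {
  # unit shorter than minUnit is not reported
  expect_equal(nrow(findTandem(strrep("ACGT", 3), minUnit = 15)), 0L)
  for (seed in 1:4) {
    set.seed(seed)
    ch <- rand_chars(300)
    if (seed >= 2) {              # 20 bp unit x3 with one mismatch in copy 2
      u <- ch[101:120]
      c2 <- u; c2[7] <- setdiff(c("A", "C", "G", "T"), u[7])[1]
      ch[121:140] <- c2; ch[141:160] <- u
    }
    got <- findTandem(paste(ch, collapse = ""))
    want <- oracle_tandem(ch)
    expect_identical(motif_sig(got, c("start1", "end1", "unit_length", "copies")),
                     motif_sig(want, c("start1", "end1", "unit_length", "copies")))
    if (seed >= 2) {
      hit <- got[got$unit_length == 20 & got$copies == 3, ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$identity, 0.95)
    }
  }
})

test_that("every retained motif satisfies its class thresholds", {
  sim <- simulatePlastomes(
    simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                     geneSet = "mini", rootRepeats = 6), seed = 4)
  rec <- leafRecords(sim)[[3]]
  q <- detectQuadripartite(rec, minIR = 1500)
  m <- motifs(scanRepeats(rec, quad = q))
  expect_true(all(m$identity >= 0.9 - 1e-12))
  expect_true(all(m$unit_length[m$type == "dispersed"] >= 30))
  expect_true(all(m$unit_length[m$type == "tandem"] >= 15))
  expect_true(all(m$unit_length[m$type == "palindromic"] >= 20))
  expect_true(all(m$gap[m$type == "palindromic"] <= 3000))
})

test_that("dispersed+palindromic repertoire is reverse-complement invariant", {
  set.seed(6)
  ch <- rand_chars(1500)
  ch[501:545] <- ch[101:145]                 # dispersed pair
  ch[1101:1125] <- o_revcomp(ch[1001:1025])  # palindrome
  s <- paste(ch, collapse = "")
  rc <- paste(o_revcomp(ch), collapse = "")
  n <- length(ch)
  fwd <- rbind(findDispersed(s), findPalindromic(s))
  rev_ <- rbind(findDispersed(rc), findPalindromic(rc))
  # map motifs found on the reverse complement back to original coordinates
  mapped <- data.frame(start1 = n - rev_$end2 + 1, end1 = n - rev_$start2 + 1,
                       start2 = n - rev_$end1 + 1, end2 = n - rev_$start1 + 1)
  # 1:1 correspondence: every motif has exactly one counterpart whose two
  # copies overlap its own (coordinates may differ by a few bases because
  # overlap-merging picks one representative window per repeat)
  expect_equal(nrow(fwd), nrow(mapped))
  for (i in seq_len(nrow(fwd))) {
    ov <- mapped$start1 <= fwd$end1[i] & mapped$end1 >= fwd$start1[i] &
      mapped$start2 <= fwd$end2[i] & mapped$end2 >= fwd$start2[i]
    expect_equal(sum(ov), 1L)
  }
})

test_that("overlap resolution gives tandem priority and merges contained motifs", {
  set.seed(44)
  ch <- rand_chars(400)
  u <- ch[101:130]
  ch[131:160] <- u; ch[161:190] <- u   # 30 bp unit x3 => also a 30 bp pair
  rec <- genomeRecord(paste(ch, collapse = ""), id = "toy")
  disp <- findDispersed(paste(ch, collapse = ""))
  tand <- findTandem(paste(ch, collapse = ""))
  pali <- findPalindromic(paste(ch, collapse = ""))
  expect_gt(nrow(disp), 0)     # the array is detectable as dispersed too
  expect_true(any(tand$unit_length == 30 & tand$copies == 3))
  rs <- resolveAndClassify(disp, tand, pali, rec)
  m <- motifs(rs)
  inarr <- m$start1 >= 95 & m$start1 <= 195
  expect_true(all(m$type[inarr] == "tandem"))  # reported once, as tandem
})

test_that("repeats joining two distinct tRNAs are reclassified as similarity", {
  set.seed(45)
  ch <- rand_chars(600)
  ch[401:474] <- ch[101:174]   # 74 bp duplication = two identical "tRNAs"
  feat <- data.frame(kind = c("gene", "tRNA", "gene", "tRNA"),
                     name = c("trnfM(CAU)", "trnfM(CAU)", "trnP(UGG)", "trnP(UGG)"),
                     start = c(101, 101, 401, 401), end = c(174, 174, 474, 474),
                     strand = "+", feature_id = 1:4)
  rec <- genomeRecord(paste(ch, collapse = ""), id = "g1", features = feat)
  rs <- resolveAndClassify(findDispersed(paste(ch, collapse = "")),
                           findTandem(paste(ch, collapse = "")),
                           findPalindromic(paste(ch, collapse = "")), rec)
  m <- motifs(rs)
  expect_true(any(m$type == "similarity"))
  # similarity repeats never enter the character matrix
  rec2 <- genomeRecord(paste(ch, collapse = ""), id = "g2", features = feat)
  rs2 <- resolveAndClassify(findDispersed(paste(ch, collapse = "")),
                            findTandem(paste(ch, collapse = "")),
                            findPalindromic(paste(ch, collapse = "")), rec2)
  M <- repeatBinaryMatrix(list(rs, rs2))
  expect_false(any(grepl("similarity", colnames(characterStates(M)))))
})

test_that("location class distinguishes coding, noncoding and spanning repeats", {
  set.seed(46)
  ch <- rand_chars(500)
  ch[301:340] <- ch[101:140]
  feat <- data.frame(kind = c("gene", "CDS"), name = "g",
                     start = 90, end = 150, strand = "+", feature_id = 1:2)
  rec <- genomeRecord(paste(ch, collapse = ""), features = feat)
  m <- motifs(resolveAndClassify(findDispersed(paste(ch, collapse = "")),
                                 findTandem(paste(ch, collapse = "")),
                                 findPalindromic(paste(ch, collapse = "")), rec))
  hit <- m[m$start1 <= 101 & m$end1 >= 140, ]
  expect_equal(hit$location_class, "both")  # copy 1 coding, copy 2 not
})

test_that("two identical genomes share every repeat; none is unique", {
  sim <- simulatePlastomes(
    simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                     geneSet = "mini", codingFactor = 0, noncodingFactor = 0,
                     indelRate = 0, repeatBirthRate = 0, rootRepeats = 6,
                     inversions = list()), seed = 91)
  recs <- leafRecords(sim)[1:2]
  sets <- lapply(recs, function(r)
    scanRepeats(r, quad = detectQuadripartite(r, minIR = 1500)))
  sh <- sharedRepeats(sets)
  expect_gt(sh$shared_all, 0)
  expect_true(all(sh$unique_per_taxon == 0))
})

test_that("shared/unique counts reproduce the planted repeat history", {
  # substitutions/indels off: gains stay exact copies, so characters
  # matched by (type, length, context) must recover the planted history
  # wherever distinct planted repeats do not collide in the same spacer
  cfg <- simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                          geneSet = "mini", codingFactor = 0,
                          noncodingFactor = 0, indelRate = 0,
                          repeatBirthRate = 2000, rootRepeats = 5,
                          inversions = list())
  sim <- simulatePlastomes(cfg, seed = 23)
  tr <- truthLog(sim)
  gains <- tr$repeat_gains
  expect_gt(nrow(gains), 0)
  sets <- lapply(leafRecords(sim), function(r)
    scanRepeats(r, quad = detectQuadripartite(r, minIR = 1500)))
  sh <- sharedRepeats(sets)
  # root repeats in spacers untouched by any later gain are shared by all
  root_sp <- unlist(strsplit(tr$root_repeats$region, "~", fixed = TRUE))
  clean_root <- !root_sp[seq_len(nrow(tr$root_repeats))] %in% gains$region &
    !vapply(strsplit(tr$root_repeats$region, "~", fixed = TRUE),
            function(x) any(x %in% gains$region), logical(1))
  expect_gte(sh$shared_all, sum(clean_root))
  # terminal-branch gains in spacers hit exactly once are leaf-unique
  term <- gains[!grepl(",", gains$leaves), , drop = FALSE]
  lonely <- term[!term$region %in% c(root_sp,
                                     gains$region[duplicated(gains$region)]), ,
                 drop = FALSE]
  for (tx in unique(lonely$leaves))
    expect_gte(sh$unique_per_taxon[[tx]], sum(lonely$leaves == tx))
})

test_that("the repeat matrix encodes presence/absence with fixed taxon order", {
  cfg <- simulationConfig(lscLength = 9000, sscLength = 3000, irLength = 3000,
                          geneSet = "mini", codingFactor = 0,
                          noncodingFactor = 0, indelRate = 0,
                          repeatBirthRate = 4000, rootRepeats = 3,
                          inversions = list())
  sim <- simulatePlastomes(cfg, seed = 29)
  sets <- lapply(leafRecords(sim), function(r)
    scanRepeats(r, quad = detectQuadripartite(r, minIR = 1500)))
  M <- repeatBinaryMatrix(sets)
  expect_setequal(taxa(M), names(leafRecords(sim)))
  st <- characterStates(M)
  expect_true(all(st %in% c("0", "1")))
  expect_true(all(colSums(st == "1") >= 1))  # no all-absent characters
  # a constant (all-present) character contributes zero steps
  tr <- bambooTree(6)
  const <- characterMatrix(matrix("1", 6, 1, dimnames = list(taxa(M)[1:6], NULL)))
  expect_equal(fitchLength(tr, const), 0)
})
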