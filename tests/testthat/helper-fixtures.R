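# Shared fixtures, built in code once per test run.

# small toy genome + annotation + recorded brute-force DRACH truth
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_genome(
      n_chrom = 2L, chrom_length = 20000L, n_genes = 8L, seed = 101L)
    cache
  }
})

# brute-force per-read pileup oracle: walk each SAM record's CIGAR and
# extract the read base laid onto a given reference position; excludes
# deletions/clips at the site. Independent of Rsamtools::pileup.
oracle_pileup <- function(sam_path, chrom, pos) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  bases <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (f[3] != chrom) next
    ref <- as.integer(f[4])   # leftmost reference position
    cig <- f[6]; seq <- f[10]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    qi <- 1L; ri <- ref
    hit <- NA_character_
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        if (pos >= ri && pos < ri + len) {
          hit <- substr(seq, qi + (pos - ri), qi + (pos - ri))
        }
        qi <- qi + len; ri <- ri + len
      } else if (type %in% c("I", "S")) {
        qi <- qi + len
      } else if (type %in% c("D", "N")) {
        if (pos >= ri && pos < ri + len) hit <- NA_character_  # deletion
        ri <- ri + len
      }
    }
    if (!is.na(hit)) bases <- c(bases, hit)
  }
  bases
}

# simple two-technique pair with planted concordant foreground sites
make_planted_pair <- function(n = 1000L, n_planted = 100L, seed = 1L) {
  withr::with_seed(seed, {
    sim <- simulate_technique_pair(n_sites = n, reproducible_fraction = 0,
                                   seed = seed + 1L)
    planted <- seq_len(n_planted)
    theta <- rbeta(n_planted, 6, 4)
    t1 <- pmax(sim$total1, 1L); t2 <- pmax(sim$total2, 1L)
    t1[planted] <- pmax(t1[planted], 20L)
    t2[planted] <- pmax(t2[planted], 20L)
    m1 <- sim$m6a1; m2 <- sim$m6a2
    m1 <- pmin(m1, t1); m2 <- pmin(m2, t2)
    m1[planted] <- rbinom(n_planted, t1[planted], theta)
    m2[planted] <- rbinom(n_planted, t2[planted], theta)
    sites <- site_set(rep("chr1", n), seq_len(n) * 10L, "+")
    se1 <- assemble_matrix(matrix(m1), matrix(t1), sites,
                           sample_record("g1", technique = "GLORI",
                                         category = "chemical"))
    se2 <- assemble_matrix(matrix(m2), matrix(t2), sites,
                           sample_record("e1", technique = "eTAM-seq",
                                         category = "enzyme"))
    list(se1 = se1, se2 = se2, planted = sites$site_id[planted],
         sites = sites)
  })
}
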