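# Hand-built pileup fixtures: exact counts, no randomness.

# One contig, arbitrary positions; ref reads fill whatever the alt reads do
# not, both split across strands at fwd_frac.
fix_pileup <- function(pos, ref = "A", alt = NA_character_, alt_reads = 0L,
                       depth = 1000L, fwd_frac = 0.5, sample_id = "S1") {
  n <- length(pos)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  alt_reads <- rep_len(as.integer(alt_reads), n)
  depth <- rep_len(as.integer(depth), n)
  fwd_frac <- rep_len(fwd_frac, n)
  cols <- paste0(rep(c("A", "C", "G", "T"), each = 2), "_",
                 c("fwd", "rev"))
  counts <- matrix(0L, n, 8L, dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    rr <- depth[i] - alt_reads[i]
    rf <- as.integer(round(rr * fwd_frac[i]))
    counts[i, paste0(ref[i], "_fwd")] <- rf
    counts[i, paste0(ref[i], "_rev")] <- rr - rf
    if (!is.na(alt[i]) && alt_reads[i] > 0) {
      af <- as.integer(round(alt_reads[i] * fwd_frac[i]))
      counts[i, paste0(alt[i], "_fwd")] <-
        counts[i, paste0(alt[i], "_fwd")] + af
      counts[i, paste0(alt[i], "_rev")] <-
        counts[i, paste0(alt[i], "_rev")] + (alt_reads[i] - af)
    }
  }
  pileup_table(rep("chr1", n), pos, ref, counts, sample_id = sample_id)
}

# Error-free plasma panel over shared positions.
fix_panel <- function(n_samples, pos, ref = "A", depth = 1000L,
                      prefix = "BG") {
  out <- list()
  for (i in seq_len(n_samples)) {
    id <- sprintf("%s%02d", prefix, i)
    out[[id]] <- fix_pileup(pos, ref = ref, depth = depth, sample_id = id)
  }
  out
}

# Minimal tissue-candidate row(s).
fix_candidates <- function(pos, ref = "A", alt = "T", tumor_af = 0.2,
                           germline_af = 0, tumor_depth = 1000L,
                           germline_depth = 1000L, caller = "mutect",
                           consequence = "nonsynonymous") {
  n <- length(pos)
  data.frame(chrom = "chr1", pos = pos, ref = rep_len(ref, n),
             alt = rep_len(alt, n), tumor_af = rep_len(tumor_af, n),
             tumor_depth = rep_len(tumor_depth, n),
             germline_af = rep_len(germline_af, n),
             germline_depth = rep_len(germline_depth, n),
             caller = rep_len(caller, n),
             consequence = rep_len(consequence, n),
             stringsAsFactors = FALSE)
}
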