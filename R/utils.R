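# Shared internal constants and helpers.

.LIBS <- c("CK", "I", "II", "III")
.STAGES <- c("I", "II", "III")
.EXCLUDED_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")

.count_cols <- function() paste0("count_", .LIBS)

# Independent RNG sub-streams per generator component: adding one component
# never perturbs the draws of another. Derived seed kept under 2^31.
.sub_seed <- function(seed, component) {
  offsets <- c(genome = 101L, loci = 211L, links = 257L, srna = 307L,
               genes = 401L, methyl = 503L, degradome = 601L,
               annotation = 701L, kmeans = 811L, pipeline = 911L)
  if (!component %in% names(offsets)) {
    stop("unknown RNG component: ", component)
  }
  as.integer((as.numeric(seed) + 1000 * offsets[[component]]) %% 2147483629)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Library totals attached to a count table (clean-read totals for RPM).
.get_totals <- function(counts, library_totals = NULL) {
  if (!is.null(library_totals)) {
    tot <- library_totals
  } else {
    tot <- attr(counts, "library_totals")
  }
  if (is.null(tot)) stop("library totals missing: supply `library_totals`")
  if (is.null(names(tot))) names(tot) <- .LIBS
  if (!all(.LIBS %in% names(tot))) {
    stop("library totals must be named for libraries: ",
         paste(.LIBS, collapse = ", "))
  }
  tot <- tot[.LIBS]
  if (any(tot <= 0)) stop("library totals must be positive")
  tot
}

.count_matrix <- function(counts) {
  cc <- .count_cols()
  if (!all(cc %in% names(counts))) {
    stop("count table must have columns: ", paste(cc, collapse = ", "))
  }
  m <- as.matrix(counts[, cc])
  colnames(m) <- .LIBS
  storage.mode(m) <- "double"
  m
}
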