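#' Gene sequences for the simulator
#'
#' A `gene_seq` holds the coding sequence the simulator runs on: the DNA
#' string (length a multiple of 3), the derived codons (codon `i` spans
#' nucleotides `3i - 2 .. 3i`), a per-codon translation-rate class
#' (`"A"`, `"B"` or `"C"`) or an explicit per-codon rate, the methionine
#' (ATG) codon positions, and any sequence-specific pause/arrest site
#' annotations.
#'
#' @param dna A single DNA string (characters ACGT), length a multiple of 3.
#'   The final codon is treated as the stop codon.
#' @param classes Codon-class table, a data frame with columns `codon` and
#'   `class`; defaults to the table shipped in
#'   `inst/extdata/codon_classes.tsv` (see [codon_class_table()]).
#' @param specific_rates Optional named numeric vector of explicit activation
#'   rates for particular codons (e.g. `c(GAG = 2.5)`); these override the
#'   class rate wherever that codon occurs.
#' @param class_override Optional character vector (length = number of
#'   codons, `NA` to keep the mapped class) forcing the class of individual
#'   codon positions, used e.g. to insert a slow-to-translate stretch.
#'
#' @return An object of class `gene_seq`.
#' @seealso [load_fasta()], [generate_random_gene()], [make_lacz_fixture()],
#'   [annotate_site()]
#' @export
gene_sequence <- function(dna, classes = codon_class_table(),
                          specific_rates = NULL, class_override = NULL) {
  dna <- toupper(as.character(dna))
  stopifnot(length(dna) == 1L)
  n <- nchar(dna)
  if (n < 6) stop("gene must have at least 2 codons", call. = FALSE)
  if (n %% 3 != 0) {
    stop("sequence length (", n, ") is not a multiple of 3", call. = FALSE)
  }
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("non-ACGT character '", chars[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  codons <- substring(dna, seq(1, n, by = 3), seq(3, n, by = 3))
  hit <- match(codons, classes$codon)
  if (anyNA(hit)) {
    stop("codon ", codons[which(is.na(hit))[1]],
         " has no entry in the codon-class table", call. = FALSE)
  }
  cls <- classes$class[hit]
  # the class table may carry explicit rates for individual codons; those
  # take precedence over the class rate (and are themselves overridden by
  # the specific_rates argument)
  table_rate <- if ("rate" %in% names(classes)) {
    as.numeric(classes$rate)[hit]
  } else rep(NA_real_, length(codons))
  cls[!is.na(table_rate)] <- "A"  # placeholder; the explicit rate wins
  if (!is.null(class_override)) {
    stopifnot(length(class_override) == length(codons))
    keep <- !is.na(class_override)
    cls[keep] <- class_override[keep]
  }
  if (!all(cls %in% c("A", "B", "C"))) {
    stop("codon classes must be A, B or C", call. = FALSE)
  }
  rate <- table_rate
  if (!is.null(specific_rates)) {
    stopifnot(is.numeric(specific_rates), !is.null(names(specific_rates)))
    hit <- match(codons, names(specific_rates))
    rate[!is.na(hit)] <- specific_rates[hit[!is.na(hit)]]
  }
  structure(list(
    nucleotides = dna,
    length = n,
    n_codons = n %/% 3L,
    codons = codons,
    class = cls,
    rate = rate,
    met_positions = which(codons == "ATG"),
    annotations = tibble::tibble(
      position = integer(), kind = character(),
      probability = double(), mean_duration_s = double())
  ), class = "gene_seq")
}

#' @export
print.gene_seq <- function(x, ...) {
  cat("gene_seq: ", x$length, " nt (", x$n_codons, " codons), ",
      length(x$met_positions), " methionine codon(s), ",
      nrow(x$annotations), " annotated site(s)\n", sep = "")
  invisible(x)
}

#' @describeIn gene_sequence One row per codon: `codon_index`, `codon`,
#'   `class`, `rate`, `is_met`.
#' @param x A `gene_seq`.
#' @param ... Unused.
#' @export
tidy.gene_seq <- function(x, ...) {
  tibble::tibble(
    codon_index = seq_len(x$n_codons),
    codon = x$codons,
    class = x$class,
    rate = x$rate,
    is_met = x$codons == "ATG"
  )
}

#' Default codon-class and codon-frequency tables
#'
#' `codon_class_table()` reads a codon-to-class map (columns `codon`,
#' `class`, optionally `rate` for codons with an explicit measured rate that
#' overrides the class); the shipped default assigns classes A/B/C from
#' E. coli codon-usage tertiles and covers all 64 codons.
#' `codon_frequency_table()` reads sense-codon frequencies (columns `codon`,
#' `frequency`, 61 rows summing to 1); the shipped default is standard
#' E. coli K-12 codon usage.
#'
#' @param path Path to a TSV file; `NULL` uses the shipped default.
#' @return A tibble.
#' @export
codon_class_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_classes.tsv", package = "txtlsim")
  }
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "class") %in% names(tb))) {
    stop("codon-class table needs columns 'codon' and 'class'", call. = FALSE)
  }
  if (anyDuplicated(tb$codon)) stop("duplicated codons in class table", call. = FALSE)
  if (nrow(tb) != 64) {
    stop("codon-class table must cover all 64 codons (got ", nrow(tb), ")",
         call. = FALSE)
  }
  tibble::as_tibble(tb)
}

#' @rdname codon_class_table
#' @export
codon_frequency_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_frequencies.tsv", package = "txtlsim")
  }
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "frequency") %in% names(tb))) {
    stop("frequency table needs columns 'codon' and 'frequency'", call. = FALSE)
  }
  validate_frequency_table(tb)
  tibble::as_tibble(tb)
}

validate_frequency_table <- function(tb) {
  stops <- c("TAA", "TAG", "TGA")
  if (any(tb$codon %in% stops)) {
    stop("frequency table must contain sense codons only", call. = FALSE)
  }
  if (nrow(tb) != 61 || anyDuplicated(tb$codon)) {
    stop("frequency table must list the 61 sense codons exactly once",
         call. = FALSE)
  }
  if (any(tb$frequency < 0) || abs(sum(tb$frequency) - 1) > 1e-6) {
    stop("codon frequencies must be non-negative and sum to 1 (+/- 1e-6)",
         call. = FALSE)
  }
  invisible(tb)
}

#' Load a gene from a FASTA file
#'
#' Reads the first record of a DNA FASTA file and builds a [gene_sequence()].
#' The record length must be a multiple of 3; non-ACGT characters are
#' rejected with the offending position named.
#'
#' @param path Path to a FASTA file.
#' @inheritParams gene_sequence
#' @return A `gene_seq`.
#' @export
load_fasta <- function(path, classes = codon_class_table(),
                       specific_rates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
    dna <- as.character(set[[1]])
  } else {
    lines <- readLines(path)
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no FASTA records in ", path, call. = FALSE)
    end <- if (length(starts) > 1) starts[2] - 1 else length(lines)
    dna <- paste(lines[(starts[1] + 1):end], collapse = "")
  }
  gene_sequence(dna, classes = classes, specific_rates = specific_rates)
}

#' Generate a random gene with prescribed codon frequencies
#'
#' Draws codons i.i.d. from a sense-codon frequency table (default: E. coli
#' usage) and forces the final codon to a stop codon (TAA).
#'
#' @param length_codons Total number of codons including the stop (>= 2).
#' @param frequencies Frequency table as from [codon_frequency_table()].
#' @param seed Optional integer seed for reproducibility.
#' @inheritParams gene_sequence
#' @return A `gene_seq`.
#' @export
generate_random_gene <- function(length_codons, frequencies = codon_frequency_table(),
                                 seed = NULL, classes = codon_class_table(),
                                 specific_rates = NULL) {
  stopifnot(length_codons >= 2)
  validate_frequency_table(frequencies)
  draw <- function() {
    body <- sample(frequencies$codon, length_codons - 1L, replace = TRUE,
                   prob = frequencies$frequency)
    paste(c(body, "TAA"), collapse = "")
  }
  dna <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  gene_sequence(dna, classes = classes, specific_rates = specific_rates)
}

#' LacZ-like test strands with slow-codon inserts
#'
#' Builds a synthetic 3072-nt (1024-codon) strand structurally emulating the
#' lacZ-based constructs used to probe ribosome queuing: every variant shares
#' the same 23 unevenly spread methionine (ATG) codons, and the `insert24` /
#' `insert48` variants carry a contiguous stretch of 24 or 48 slow
#' (class-C) codons at a fixed fractional position. The strand is a
#' structural emulation, not the real lacZ sequence.
#'
#' @param variant `"wt"`, `"insert24"` or `"insert48"`.
#' @param seed Seed controlling the (shared) random background sequence and
#'   methionine placement; the same seed gives the same backbone across
#'   variants.
#' @param insert_at Fractional position (0-1) of the slow-stretch start.
#' @inheritParams gene_sequence
#' @return A `gene_seq`.
#' @export
make_lacz_fixture <- function(variant = c("wt", "insert24", "insert48"),
                              seed = 1L, insert_at = 0.5,
                              classes = codon_class_table()) {
  variant <- match.arg(variant)
  n_codons <- 1024L
  n_met <- 23L
  max_insert <- 48L
  insert_start <- max(2L, min(n_codons - 1L - max_insert,
                              as.integer(round(insert_at * n_codons))))
  # methionines never fall inside the (largest) insert window, so every
  # variant shares the exact same 23 positions
  blocked <- insert_start:(insert_start + max_insert - 1L)
  backbone <- withr::with_seed(seed, {
    freq <- codon_frequency_table()
    body_tb <- freq[freq$codon != "ATG", ]  # ATG placed explicitly below
    body <- sample(body_tb$codon, n_codons - 1L, replace = TRUE,
                   prob = body_tb$frequency)
    met_at <- sort(c(1L, sample(setdiff(2:(n_codons - 1L), blocked),
                                n_met - 1L)))
    body[met_at] <- "ATG"
    c(body, "TAA")
  })
  n_insert <- switch(variant, wt = 0L, insert24 = 24L, insert48 = 48L)
  override <- rep(NA_character_, n_codons)
  codons <- backbone
  if (n_insert > 0) {
    idx <- insert_start:(insert_start + n_insert - 1L)
    codons[idx] <- "GAG"   # glutamate stretch
    override[idx] <- "C"   # forced slow-to-translate class
  }
  gene_sequence(paste(codons, collapse = ""), classes = classes,
                class_override = override)
}

#' Annotate a sequence-specific pause or arrest site
#'
#' Attaches a long-pause or arrest site to a nucleotide position. When an
#' RNAp first arrives at the annotated nucleotide it enters the paused
#' (or arrested) state with the given probability, and is then released at
#' rate `1 / mean_duration_s`. Long pauses remain releasable by collisions
#' with a trailing RNAp; arrests are not.
#'
#' @param gene A `gene_seq`.
#' @param position Nucleotide position (1-based, within the gene).
#' @param kind `"long_pause"` or `"arrest"`.
#' @param probability Probability that an arriving RNAp triggers the site.
#' @param mean_duration_s Mean dwell at the site once triggered (seconds).
#' @return The `gene_seq` with the annotation added.
#' @export
annotate_site <- function(gene, position, kind = c("long_pause", "arrest"),
                          probability, mean_duration_s) {
  stopifnot(inherits(gene, "gene_seq"))
  kind <- match.arg(kind)
  if (position < 1 || position > gene$length) {
    stop("site position ", position, " outside the gene (1..", gene$length,
         ")", call. = FALSE)
  }
  if (probability < 0 || probability > 1) {
    stop("site probability must be in [0, 1]", call. = FALSE)
  }
  if (mean_duration_s <= 0) stop("mean duration must be positive", call. = FALSE)
  gene$annotations <- dplyr::bind_rows(
    gene$annotations,
    tibble::tibble(position = as.integer(position), kind = kind,
                   probability = probability, mean_duration_s = mean_duration_s))
  gene
}

#' Read site annotations from a TSV file
#'
#' Columns: `position` (1-based nucleotide), `kind` (`long_pause` or
#' `arrest`), `probability` (0-1), `mean_duration_s` (seconds).
#'
#' @param gene A `gene_seq`.
#' @param path TSV file path.
#' @return The annotated `gene_seq`.
#' @export
load_site_annotations <- function(gene, path) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "kind", "probability", "mean_duration_s")
  if (!all(need %in% names(tb))) {
    stop("annotation file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tb))) {
    gene <- annotate_site(gene, tb$position[i], tb$kind[i], tb$probability[i],
                          tb$mean_duration_s[i])
  }
  gene
}

# per-codon activation rates resolved against the kinetic parameters
resolve_codon_rates <- function(gene, params) {
  rate <- c(A = params$k_transA, B = params$k_transB, C = params$k_transC)[gene$class]
  explicit <- !is.na(gene$rate)
  rate[explicit] <- gene$rate[explicit]
  unname(rate)
}

# gene payload handed to the C++ engine
engine_gene <- function(gene, params) {
  ann <- gene$annotations
  list(
    length = gene$length,
    codon_rates = resolve_codon_rates(gene, params),
    is_met = gene$codons == "ATG",
    site_pos = as.integer(ann$position),
    site_kind = as.integer(ann$kind == "arrest"),
    site_prob = as.double(ann$probability),
    site_dur = as.double(ann$mean_duration_s)
  )
}
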