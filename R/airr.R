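#' Read BCR chain annotations from an AIRR rearrangement TSV
#'
#' Parses one-row-per-chain rearrangement tables (AIRR-C column names).
#' Allele suffixes (`*01` etc.) are stripped from V/J/C calls so all
#' downstream matching is gene-level. Rows lacking a CDR3 amino-acid
#' sequence are dropped (with a message reporting how many), matching the
#' upstream practice of discarding contigs without CDR3s.
#'
#' Required columns: `cell_id`, `locus`, `v_call`, `j_call`, `productive`,
#' `cdr3_aa` (or `junction_aa`), `sequence`. Optional: `c_call`,
#' `cdr3`/`junction`, `duplicate_count` (UMI), `vj_in_frame`, `donor_id`.
#'
#' @param path path to a tab-separated AIRR rearrangement file.
#' @return data.frame of chain records with columns `cell_id`, `locus`,
#'   `v_call`, `j_call`, `c_call`, `cdr3_nt`, `cdr3_aa`, `productive`,
#'   `in_frame`, `umi_count`, `v_sequence`, `donor_id`.
#' @export
read_airr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty AIRR file: ", path)
    return(empty_chains())
  }
  if (!"cdr3_aa" %in% names(df) && "junction_aa" %in% names(df))
    df$cdr3_aa <- df$junction_aa
  if (!"cdr3_nt" %in% names(df)) {
    if ("cdr3" %in% names(df)) df$cdr3_nt <- df$cdr3
    else if ("junction" %in% names(df)) df$cdr3_nt <- df$junction
    else df$cdr3_nt <- NA_character_
  }
  required <- c("cell_id", "locus", "v_call", "j_call", "productive",
                "cdr3_aa", "sequence")
  miss <- setdiff(required, names(df))
  if (length(miss))
    cs_input_error(paste0("AIRR file missing required column(s): ",
                          paste(miss, collapse = ", ")))
  drop <- is.na(df$cdr3_aa) | df$cdr3_aa == "" |
    is.na(df$cell_id) | df$cell_id == "" |
    is.na(df$v_call) | df$v_call == ""
  if (any(drop))
    message(sum(drop), " AIRR row(s) dropped (missing cell id, V call or CDR3)")
  df <- df[!drop, , drop = FALSE]
  strip <- function(x) sub("\\*.*$", "", x)
  prod <- toupper(df$productive) %in% c("T", "TRUE", "1")
  inframe <- if ("vj_in_frame" %in% names(df))
    toupper(df$vj_in_frame) %in% c("T", "TRUE", "1") else prod
  data.frame(
    cell_id = df$cell_id,
    locus = df$locus,
    v_call = strip(df$v_call),
    j_call = strip(df$j_call),
    c_call = if ("c_call" %in% names(df)) strip(df$c_call) else NA_character_,
    cdr3_nt = df$cdr3_nt,
    cdr3_aa = df$cdr3_aa,
    productive = prod,
    in_frame = inframe,
    umi_count = if ("duplicate_count" %in% names(df))
      suppressWarnings(as.integer(df$duplicate_count)) else NA_integer_,
    v_sequence = df$sequence,
    donor_id = if ("donor_id" %in% names(df)) df$donor_id else NA_character_,
    stringsAsFactors = FALSE)
}

empty_chains <- function() {
  data.frame(cell_id = character(), locus = character(), v_call = character(),
             j_call = character(), c_call = character(), cdr3_nt = character(),
             cdr3_aa = character(), productive = logical(),
             in_frame = logical(), umi_count = integer(),
             v_sequence = character(), donor_id = character(),
             stringsAsFactors = FALSE)
}

#' Write chain records to an AIRR rearrangement TSV
#'
#' Emits AIRR-C v1 column names (`cell_id`, `locus`, `v_call`, `j_call`,
#' `c_call`, `productive`, `junction`, `junction_aa`, `cdr3`, `cdr3_aa`,
#' `duplicate_count`, `sequence`, `donor_id`), with `productive` encoded
#' as `T`/`F`.
#'
#' @param chains data.frame as produced by [read_airr()] or the simulator.
#' @param path output path.
#' @export
write_airr <- function(chains, path) {
  out <- data.frame(
    sequence_id = sprintf("%s_%s", chains$cell_id, chains$locus),
    cell_id = chains$cell_id,
    locus = chains$locus,
    v_call = chains$v_call,
    j_call = chains$j_call,
    c_call = chains$c_call,
    productive = ifelse(chains$productive, "T", "F"),
    vj_in_frame = ifelse(chains$in_frame, "T", "F"),
    junction = chains$cdr3_nt,
    junction_aa = chains$cdr3_aa,
    cdr3 = chains$cdr3_nt,
    cdr3_aa = chains$cdr3_aa,
    duplicate_count = chains$umi_count,
    sequence = chains$v_sequence,
    donor_id = chains$donor_id,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
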