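#' qPCR Ct table
#'
#' Long-format Ct values with housekeeping normalization targets and a
#' control sample. Columns: `sample_id`, `biological_replicate`,
#' `technical_replicate`, `gene`, `ct` (cycles).
#'
#' @param data data.frame with the columns above (`technical_replicate`
#'   optional; defaults to 1).
#' @param housekeeping character vector of housekeeping gene names (e.g.
#'   GAPDH, ACTB); averaged on the Ct scale when several are given.
#' @param control id of the control/reference sample (e.g. untreated WT).
#' @return validated object of class `ct_table`.
#' @export
ct_table <- function(data, housekeeping, control) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("sample_id", "biological_replicate", "gene", "ct")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"technical_replicate" %in% names(data)) data$technical_replicate <- 1L
  if (!all(is.finite(data$ct)) || any(data$ct <= 0) || any(data$ct >= 45))
    stop("Ct values must be finite and in (0, 45) cycles")
  if (!control %in% data$sample_id)
    stop("control sample not present: ", control)
  for (s in unique(data$sample_id)) {
    hk <- housekeeping %in% data$gene[data$sample_id == s]
    if (!all(hk))
      stop("sample ", s, " lacks housekeeping gene(s): ",
           paste(housekeeping[!hk], collapse = ", "))
  }
  structure(list(data = data, housekeeping = housekeeping, control = control),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("<ct_table> ", length(unique(x$data$sample_id)), " samples, ",
      length(unique(x$data$gene)), " genes, control = ", x$control,
      ", housekeeping: ", paste(x$housekeeping, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per biological replicate: technical replicates are averaged;
#' `dCt = Ct_gene - mean(Ct_housekeeping)` within the same sample and
#' replicate; `ddCt = dCt_sample - dCt_control`, pairing control replicates
#' by `biological_replicate` id when the control ran the same replicate, else
#' using the control's mean dCt; `log2FC = -ddCt` (amplification efficiency
#' fixed at 2, no efficiency correction). Matrix cells are the mean over
#' biological replicates with the SD reported alongside; the control column
#' is identically 0 by construction.
#'
#' @param ct a [ct_table()].
#' @param gene_order,sample_order optional explicit orderings for
#'   heatmap-ready output (e.g. genes grouped by germ-layer panel, samples by
#'   timepoint).
#' @return object of class `fold_change_matrix`: `log2fc` and `sd` (genes x
#'   samples matrices), `n_replicates`, `control`, `housekeeping`.
#' @export
compute_log2fc <- function(ct, gene_order = NULL, sample_order = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  d <- ct$data
  # technical replicates averaged per (sample, bio rep, gene)
  tech <- stats::aggregate(ct ~ sample_id + biological_replicate + gene,
                           data = d, FUN = mean)
  hk <- tech[tech$gene %in% ct$housekeeping, ]
  hk_mean <- stats::aggregate(ct ~ sample_id + biological_replicate,
                              data = hk, FUN = mean)
  names(hk_mean)[names(hk_mean) == "ct"] <- "hk_ct"
  m <- merge(tech, hk_mean, by = c("sample_id", "biological_replicate"))
  m$dct <- m$ct - m$hk_ct

  ctrl <- m[m$sample_id == ct$control, c("biological_replicate", "gene", "dct")]
  names(ctrl)[names(ctrl) == "dct"] <- "dct_ctrl_rep"
  ctrl_mean <- stats::aggregate(dct_ctrl_rep ~ gene, data = ctrl, FUN = mean)
  names(ctrl_mean)[2] <- "dct_ctrl_mean"

  m <- merge(m, ctrl, by = c("biological_replicate", "gene"), all.x = TRUE)
  m <- merge(m, ctrl_mean, by = "gene", all.x = TRUE)
  if (any(is.na(m$dct_ctrl_mean)))
    stop("control sample lacks Ct for gene(s): ",
         paste(unique(m$gene[is.na(m$dct_ctrl_mean)]), collapse = ", "))
  m$ddct <- m$dct - ifelse(is.na(m$dct_ctrl_rep), m$dct_ctrl_mean, m$dct_ctrl_rep)
  m$log2fc <- -m$ddct

  genes <- gene_order %||% sort(setdiff(unique(m$gene), ct$housekeeping))
  samples <- sample_order %||% unique(d$sample_id)
  agg_mean <- stats::aggregate(log2fc ~ gene + sample_id, data = m, FUN = mean)
  agg_sd <- stats::aggregate(log2fc ~ gene + sample_id, data = m,
                             FUN = function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)
  agg_n <- stats::aggregate(log2fc ~ gene + sample_id, data = m, FUN = length)
  mk <- function(a) {
    M <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    a <- a[a$gene %in% genes & a$sample_id %in% samples, ]
    M[cbind(match(a$gene, genes), match(a$sample_id, samples))] <- a$log2fc
    M
  }
  structure(list(log2fc = mk(agg_mean), sd = mk(agg_sd),
                 n_replicates = mk(agg_n),
                 control = ct$control, housekeeping = ct$housekeeping),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, digits = 3, ...) {
  cat("<fold_change_matrix> log2 fold change vs ", x$control,
      " (housekeeping: ", paste(x$housekeeping, collapse = ", "), ")\n", sep = "")
  print(round(x$log2fc, digits))
  invisible(x)
}

#' Write a fold-change matrix as wide CSV
#'
#' Emits `log2FC_<sample>` and `sd_<sample>` columns per gene, ready for
#' heatmap plotting.
#'
#' @param x a `fold_change_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_log2fc_csv <- function(x, path) {
  stopifnot(inherits(x, "fold_change_matrix"))
  df <- data.frame(gene = rownames(x$log2fc), stringsAsFactors = FALSE)
  for (s in colnames(x$log2fc)) {
    df[[paste0("log2FC_", s)]] <- x$log2fc[, s]
    df[[paste0("sd_", s)]] <- x$sd[, s]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format Ct CSV
#'
#' @param path CSV with columns `sample_id`, `biological_replicate`,
#'   `technical_replicate`, `gene`, `ct`.
#' @param housekeeping,control passed to [ct_table()].
#' @return a [ct_table()].
#' @export
read_ct_csv <- function(path, housekeeping, control) {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE),
           housekeeping = housekeeping, control = control)
}
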