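CNV_STATES <- c("het_deletion", "hom_deletion", "duplication")

#' Construct a per-target read-depth matrix
#'
#' @param targets data frame with columns `gene`, `label`, `chromosome`,
#'   `start`, `end` (as from [panel_targets()]), rows in genomic order
#'   within each gene
#' @param depth numeric matrix, targets x samples, of non-negative mean
#'   read depths; column names are sample ids
#' @return an object of class `depth_matrix`
#' @export
depth_matrix <- function(targets, depth) {
  stopifnot(is.matrix(depth), nrow(targets) == nrow(depth))
  if (is.null(colnames(depth))) stop("depth matrix must have sample names")
  if (any(depth < 0)) stop("negative read depths are not allowed")
  structure(list(targets = targets, depth = depth), class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("<depth_matrix> ", nrow(x$targets), " targets (",
      length(unique(x$targets$gene)), " genes) x ", ncol(x$depth),
      " samples\n", sep = "")
  invisible(x)
}

#' Write a depth matrix as TSV (targets rows, sample columns)
#' @param dm a `depth_matrix`
#' @param path output path
#' @return invisibly, the path
#' @export
write_depth_matrix <- function(dm, path) {
  out <- cbind(dm$targets, as.data.frame(dm$depth, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth matrix TSV written by [write_depth_matrix()]
#' @param path TSV path
#' @return a `depth_matrix`
#' @export
read_depth_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("gene", "label", "chromosome", "start", "end")
  depth <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
  depth_matrix(x[, meta], depth)
}

#' Normalize a depth matrix to copy-number ratios
#'
#' Two-step normalization: (1) library-size correction — every sample
#' column is scaled so all samples share the same median per-target depth;
#' (2) target-efficiency correction — every target row is divided by its
#' mean across the reference samples. After both steps a diploid target in
#' a typical sample has ratio close to 1, a heterozygous deletion close to
#' 0.5, a duplication close to 1.5.
#'
#' Targets whose reference row mean is zero cannot be normalized; they are
#' flagged uncallable (ratio `NA`) and skipped by the caller.
#'
#' @param dm a `depth_matrix`
#' @param reference_samples sample ids defining expected diploid depth
#'   (default: all samples)
#' @return a `depth_matrix` whose `depth` holds normalized ratios, with an
#'   added logical element `uncallable` (one per target)
#' @export
normalize_depth <- function(dm, reference_samples = colnames(dm$depth)) {
  stopifnot(inherits(dm, "depth_matrix"))
  missing_s <- setdiff(reference_samples, colnames(dm$depth))
  if (length(missing_s) > 0) {
    stop("reference sample(s) not in depth matrix: ",
         paste(missing_s, collapse = ", "))
  }
  d <- dm$depth
  col_med <- apply(d, 2, stats::median)
  if (any(col_med == 0)) {
    stop("sample(s) with all-zero (median-zero) depth: ",
         paste(colnames(d)[col_med == 0], collapse = ", "))
  }
  target_med <- stats::median(col_med)
  d <- sweep(d, 2, target_med / col_med, `*`)
  ref_mean <- rowMeans(d[, reference_samples, drop = FALSE])
  uncallable <- ref_mean == 0
  ratios <- sweep(d, 1, ref_mean, `/`)
  ratios[uncallable, ] <- NA_real_
  out <- dm
  out$depth <- ratios
  out$uncallable <- uncallable
  out
}

#' Caller parameters for read-depth CNV detection
#'
#' A target is anomalous when `|z| >= z_min`, where z is the test ratio
#' standardized against the reference samples' ratios at that target. A
#' candidate event spans a maximal run of at least `min_targets`
#' consecutive same-direction anomalous targets within one gene; up to
#' `gap_tolerance` consecutive uncallable targets inside a run are
#' skipped without breaking it. The run additionally needs a combined
#' significance of `|mean z| * sqrt(n_targets) >= z_call`, which guards
#' against single low-coverage targets drifting over a band edge. The
#' run's mean normalized ratio assigns the state: homozygous deletion
#' below `hom_del_max`; heterozygous deletion within `het_del_band`;
#' duplication within `dup_band`; runs outside every band are discarded.
#'
#' @param min_targets minimum run length (default 1: single-exon events
#'   are real and reportable)
#' @param z_min minimum |z| per target (default 3)
#' @param z_call minimum combined run significance
#'   `|mean z| * sqrt(n_targets)` (default 5)
#' @param hom_del_max upper ratio bound for homozygous deletion (default 0.15)
#' @param het_del_band ratio band for heterozygous deletion (default 0.35-0.65)
#' @param dup_band ratio band for duplication (default 1.35-1.75)
#' @param gap_tolerance uncallable targets tolerated inside a run (default 0)
#' @return a list of class `caller_params`
#' @export
caller_params <- function(min_targets = 1L, z_min = 3, z_call = 5,
                          hom_del_max = 0.15,
                          het_del_band = c(0.35, 0.65),
                          dup_band = c(1.35, 1.75),
                          gap_tolerance = 0L) {
  stopifnot(min_targets >= 1, z_min >= 0, z_call >= 0,
            length(het_del_band) == 2, length(dup_band) == 2)
  structure(list(min_targets = as.integer(min_targets), z_min = z_min,
                 z_call = z_call,
                 hom_del_max = hom_del_max, het_del_band = het_del_band,
                 dup_band = dup_band,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "caller_params")
}

empty_cnv_calls <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             region = character(0), state = character(0),
             breakpoint_tag = character(0), n_targets = integer(0),
             first_target = character(0), last_target = character(0),
             mean_ratio = numeric(0), mean_z = numeric(0),
             stringsAsFactors = FALSE)
}

#' Call CNVs in one test sample against a reference panel
#'
#' Detects deletions and duplications from differences in normalized read
#' depth between the test sample and a panel of CNV-free reference
#' samples. Detection and typing are separated: per target, the test
#' ratio is standardized against the reference ratios (z-score), and
#' targets with `|z| >= z_min` are flagged as anomalous; maximal runs of
#' consecutive same-direction anomalous targets within a gene become
#' candidate events, and each run's mean ratio assigns the copy state
#' (run means are much less noisy than single targets, so multi-exon
#' events are typed reliably). Runs whose mean ratio lands outside every
#' state band are dropped as noise. Deterministic given inputs.
#'
#' @param dm a raw (unnormalized) `depth_matrix` containing test and
#'   reference samples
#' @param test_sample sample id to test (must not be in the reference set)
#' @param reference_samples ids of at least 3 CNV-free samples
#' @param params a [caller_params()] object
#' @return data frame of calls: `sample_id`, `gene`, `region`, `state`,
#'   `breakpoint_tag` (`NA`; depth evidence cannot resolve breakpoints),
#'   `n_targets`, `first_target`, `last_target`, `mean_ratio`, `mean_z`
#' @export
call_cnvs <- function(dm, test_sample, reference_samples,
                      params = caller_params()) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (test_sample %in% reference_samples) {
    stop("test sample must not be part of the reference set")
  }
  if (length(reference_samples) < 3) {
    stop("need at least 3 reference samples, got ",
         length(reference_samples))
  }
  sub <- dm
  keep <- c(reference_samples, test_sample)
  missing_s <- setdiff(keep, colnames(dm$depth))
  if (length(missing_s) > 0) {
    stop("sample(s) not in depth matrix: ", paste(missing_s, collapse = ", "))
  }
  sub$depth <- dm$depth[, keep, drop = FALSE]
  norm <- normalize_depth(sub, reference_samples)
  r_test <- norm$depth[, test_sample]
  ref <- norm$depth[, reference_samples, drop = FALSE]
  mean_ref <- rowMeans(ref)
  sd_ref <- apply(ref, 1, stats::sd)
  z <- (r_test - mean_ref) / sd_ref

  # detection: a target is anomalous when its |z| clears the threshold;
  # a z of Inf (zero reference variance, clear shift) still qualifies
  direction <- rep(0L, length(r_test))
  pass_z <- !is.na(z) & abs(z) >= params$z_min
  direction[pass_z & r_test < 1] <- -1L
  direction[pass_z & r_test > 1] <- 1L

  calls <- list()
  tg <- norm$targets
  for (gene in unique(tg$gene)) {
    idx <- which(tg$gene == gene)
    run_dir <- 0L
    run_idx <- integer(0)
    gap <- 0L
    flush <- function() {
      run_z <- if (length(run_idx) > 0) {
        abs(mean(z[run_idx])) * sqrt(length(run_idx))
      } else 0
      if (run_dir != 0L && length(run_idx) >= params$min_targets &&
            run_z >= params$z_call) {
        # typing: the run's mean ratio decides the copy state; runs whose
        # mean falls outside every band are discarded as noise
        mr <- mean(r_test[run_idx])
        state <- if (mr < params$hom_del_max) "hom_deletion"
          else if (mr >= params$het_del_band[1] &&
                     mr <= params$het_del_band[2]) "het_deletion"
          else if (mr >= params$dup_band[1] &&
                     mr <= params$dup_band[2]) "duplication"
          else NA_character_
        if (!is.na(state)) {
          labs <- tg$label[run_idx]
          calls[[length(calls) + 1L]] <<- data.frame(
            sample_id = test_sample, gene = gene,
            region = format_region(labs), state = state,
            breakpoint_tag = NA_character_,
            n_targets = length(run_idx),
            first_target = labs[1], last_target = labs[length(labs)],
            mean_ratio = mr,
            mean_z = mean(z[run_idx]),
            stringsAsFactors = FALSE)
        }
      }
      run_dir <<- 0L
      run_idx <<- integer(0)
      gap <<- 0L
    }
    for (i in idx) {
      if (norm$uncallable[i]) {
        gap <- gap + 1L
        if (gap > params$gap_tolerance) flush()
        next
      }
      gap <- 0L
      d <- direction[i]
      if (d == 0L) {
        flush()
      } else if (d == run_dir) {
        run_idx <- c(run_idx, i)
      } else {
        flush()
        run_dir <- d
        run_idx <- i
      }
    }
    flush()
  }
  if (length(calls) == 0) return(empty_cnv_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Format a run of target labels as a region string
#'
#' Single target: its label (`"Exon 4"`). Runs of plain exons:
#' `"Exons 2-6"`. Mixed runs: `"5'UTR - Exon 1"`.
#'
#' @param labels character vector of target labels, in order
#' @return a single region string
#' @export
format_region <- function(labels) {
  stopifnot(length(labels) >= 1)
  if (length(labels) == 1) return(labels)
  first <- labels[1]
  last <- labels[length(labels)]
  nums <- regmatches(c(first, last), regexec("^Exon (\\d+)$", c(first, last)))
  if (all(lengths(nums) == 2)) {
    sprintf("Exons %s-%s", nums[[1]][2], nums[[2]][2])
  } else {
    paste(first, "-", last)
  }
}

#' Aggregate CNV calls into a unique-CNV catalogue
#'
#' Groups per-sample calls into unique CNVs. The identity of a CNV is the
#' lesion, not the carrier's zygosity: the key is (gene, region, event
#' type deletion/duplication, breakpoint tag). Calls with the same span
#' but different breakpoint tags stay distinct rows; heterozygous and
#' homozygous instances of the same deletion fall in one row, with the
#' zygosity mix summarized (e.g. `"hom x2, het"`).
#'
#' @param calls data frame of CNV calls (as from [call_cnvs()] or an
#'   external catalogue), columns `gene`, `region`, `state`, optional
#'   `breakpoint_tag`
#' @return an object of class `unique_cnv_table`: data frame with columns
#'   `gene`, `region`, `type`, `zygosity`, `breakpoint_tag`,
#'   `instances_observed`, plus attributes `unique_count` and
#'   `instance_count`
#' @export
aggregate_unique <- function(calls) {
  if (!"breakpoint_tag" %in% names(calls)) calls$breakpoint_tag <- NA_character_
  bad <- setdiff(unique(calls$state), CNV_STATES)
  if (length(bad) > 0) stop("unknown CNV state(s): ", paste(bad, collapse = ", "))
  if (nrow(calls) == 0) {
    out <- data.frame(gene = character(0), region = character(0),
                      type = character(0), zygosity = character(0),
                      breakpoint_tag = character(0),
                      instances_observed = integer(0))
    attr(out, "unique_count") <- 0L
    attr(out, "instance_count") <- 0L
    class(out) <- c("unique_cnv_table", "data.frame")
    return(out)
  }
  type <- ifelse(calls$state == "duplication", "duplication", "deletion")
  tag <- ifelse(is.na(calls$breakpoint_tag), "", calls$breakpoint_tag)
  key <- paste(calls$gene, calls$region, type, tag, sep = "\r")
  grp <- split(seq_len(nrow(calls)), key)
  rows <- lapply(grp, function(ii) {
    data.frame(gene = calls$gene[ii[1]], region = calls$region[ii[1]],
               type = type[ii[1]],
               zygosity = zygosity_summary(calls$state[ii]),
               breakpoint_tag = tag[ii[1]],
               instances_observed = length(ii), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$region, out$type, out$breakpoint_tag), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unique_count") <- nrow(out)
  attr(out, "instance_count") <- nrow(calls)
  class(out) <- c("unique_cnv_table", "data.frame")
  out
}

zygosity_summary <- function(states) {
  if (all(states == "duplication")) return("")
  n_hom <- sum(states == "hom_deletion")
  n_het <- sum(states == "het_deletion")
  part <- function(lbl, n) {
    if (n == 0) NULL else if (n == 1) lbl else sprintf("%s x%d", lbl, n)
  }
  paste(c(part("hom", n_hom), part("het", n_het)), collapse = ", ")
}

#' @export
print.unique_cnv_table <- function(x, ...) {
  cat("<unique_cnv_table> ", attr(x, "unique_count"), " unique CNVs, ",
      attr(x, "instance_count"), " total instances\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Read a unique-CNV catalogue file and expand it to per-instance calls
#'
#' The catalogue TSV has columns `gene`, `region`, `state` (one of
#' `het_deletion`, `hom_deletion`, `duplication`), `breakpoint_tag`
#' (may be empty) and `instances` (how many samples carried it). Each
#' catalogue row is expanded to `instances` call records with synthetic
#' carrier ids, suitable for [aggregate_unique()].
#'
#' @param path catalogue TSV path
#' @return data frame of per-instance calls
#' @export
read_cnv_catalogue <- function(path) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE,
                              na.strings = character(0))
  need <- c("gene", "region", "state", "breakpoint_tag", "instances")
  miss <- setdiff(need, names(cat_df))
  if (length(miss) > 0) {
    stop("CNV catalogue missing column(s): ", paste(miss, collapse = ", "))
  }
  idx <- rep(seq_len(nrow(cat_df)), cat_df$instances)
  out <- data.frame(
    sample_id = sprintf("carrier_%03d", seq_along(idx)),
    gene = cat_df$gene[idx], region = cat_df$region[idx],
    state = cat_df$state[idx],
    breakpoint_tag = ifelse(nzchar(cat_df$breakpoint_tag[idx]),
                            cat_df$breakpoint_tag[idx], NA_character_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
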