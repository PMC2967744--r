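# Clinical feature correlation layer: ordinal binning of mixed
# categorical/continuous encounter variables, pairwise-complete Spearman
# correlation with a minimum-pair rule, network thresholding, and a log-log
# degree-distribution fit.

#' Bin one clinical variable to ordinal codes
#'
#' Categorical variables with at most `max_cats` categories get one code per
#' declared category, in declared order. Categorical variables with more
#' categories are merged into `max_cats` contiguous near-equal ranges.
#' Continuous variables with a laboratory reference range `(low, high)` are
#' coded 0 below normal (`value < low`), 1 normal (`low <= value <= high`)
#' and 2 above normal; continuous variables without a range fall back to
#' tertiles. Nulls propagate.
#'
#' @param values raw column (character for categorical, numeric for
#'   continuous; NA = null).
#' @param spec the matching [variable_spec()].
#' @param max_cats maximum number of bins for categorical variables.
#' @return list with `codes` (integer, 0-based, NA for null) and
#'   `dictionary` (named character, code -> label).
#' @export
bin_variable <- function(values, spec, max_cats = 8) {
  stopifnot(inherits(spec, "variable_spec"), max_cats >= 2)
  if (spec$kind == "categorical") {
    values <- as.character(values)
    bad <- !is.na(values) & !(values %in% spec$categories)
    if (any(bad))
      stop("undeclared category in '", spec$name, "': ",
           values[which(bad)[1]])
    k <- length(spec$categories)
    pos <- match(values, spec$categories)  # 1..k, NA for null
    if (k <= max_cats) {
      codes <- pos - 1L
      dict <- stats::setNames(spec$categories, as.character(0:(k - 1)))
    } else {
      # contiguous ranges of near-equal size (sizes differ by at most 1)
      sizes <- rep(k %/% max_cats, max_cats)
      extra <- k %% max_cats
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      bin_of <- rep(seq_len(max_cats) - 1L, times = sizes)
      codes <- bin_of[pos]
      ends <- cumsum(sizes); starts <- c(1L, utils::head(ends, -1) + 1L)
      dict <- stats::setNames(
        paste(spec$categories[starts], spec$categories[ends], sep = ".."),
        as.character(seq_len(max_cats) - 1L))
    }
  } else {
    if (is.character(values)) {
      num <- suppressWarnings(as.numeric(values))
      bad <- which(!is.na(values) & values != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value in continuous '", spec$name, "': '",
             values[bad[1]], "' (entry ", bad[1], ")")
      values <- num
    }
    values <- as.numeric(values)
    if (!is.null(spec$reference_range)) {
      lo <- spec$reference_range[1]; hi <- spec$reference_range[2]
      codes <- ifelse(values < lo, 0L, ifelse(values <= hi, 1L, 2L))
      dict <- c("0" = "below normal", "1" = "normal", "2" = "above normal")
    } else {
      qs <- stats::quantile(values, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
      codes <- findInterval(values, qs)
      dict <- c("0" = "low tertile", "1" = "mid tertile", "2" = "high tertile")
    }
    codes <- as.integer(codes)
  }
  list(codes = codes, dictionary = dict)
}

#' Bin a whole encounter table
#'
#' Applies [bin_variable()] to every variable of an [gen_encounter_table()]
#' result (or any `encounter_table`).
#'
#' @param tbl an `encounter_table`.
#' @param max_cats maximum categorical bin count.
#' @return An object of class `binned_table`: `encounter_ids`, `data`
#'   (integer ordinal codes, NA for null) and `dictionaries`.
#' @export
bin_table <- function(tbl, max_cats = 8) {
  stopifnot(inherits(tbl, "encounter_table"))
  binned <- lapply(tbl$variables, function(v)
    bin_variable(tbl$data[[v$name]], v, max_cats = max_cats))
  data <- as.data.frame(lapply(binned, `[[`, "codes"))
  names(data) <- vapply(tbl$variables, `[[`, "", "name")
  structure(list(encounter_ids = tbl$encounter_ids, data = data,
                 dictionaries = stats::setNames(
                   lapply(binned, `[[`, "dictionary"), names(data))),
            class = "binned_table")
}

#' Pairwise-complete Spearman correlation with a minimum-pair rule
#'
#' Restricts both columns to indices where neither is null. If fewer than
#' `min_pairs` complete pairs remain the correlation is declared undefined
#' (never coerced to zero); likewise when a restricted column is constant.
#' Otherwise the Spearman rank correlation (average ranks for ties) is
#' returned.
#'
#' @param x,y equal-length ordinal (or numeric) columns.
#' @param min_pairs minimum number of complete pairs; default 20.
#' @return list with `rho` (NA when undefined), `n_pairs`, `defined`, and
#'   `reason` ("" / "too_few_pairs" / "constant").
#' @export
spearman_pair <- function(x, y, min_pairs = 20) {
  if (length(x) != length(y)) stop("columns must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs)
    return(list(rho = NA_real_, n_pairs = n, defined = FALSE,
                reason = "too_few_pairs"))
  xs <- x[ok]; ys <- y[ok]
  if (length(unique(xs)) < 2 || length(unique(ys)) < 2) {
    message("constant column after pairwise restriction; correlation undefined")
    return(list(rho = NA_real_, n_pairs = n, defined = FALSE,
                reason = "constant"))
  }
  list(rho = stats::cor(xs, ys, method = "spearman"), n_pairs = n,
       defined = TRUE, reason = "")
}

#' Build the clinical attribute correlation network
#'
#' Pre-filters attributes that can never yield a defined correlation (fewer
#' than `min_pairs` non-null entries overall, or constant after binning),
#' logging the dropped count, then evaluates every remaining attribute pair
#' with [spearman_pair()] and keeps edges with `rho >= rho_min`
#' (`|rho| >= rho_min` when `use_abs`). Pairs failing the minimum-pair rule
#' are recorded as undefined, never treated as zero.
#'
#' @param tbl a [bin_table()] result.
#' @param rho_min correlation threshold; default 0.95.
#' @param min_pairs minimum complete pairs per correlation; default 20.
#' @param use_abs threshold on `|rho|` instead of signed `rho`.
#' @return An object of class `clinical_network`: `nodes`, `edges`
#'   (`a`, `b`, `rho`, `n_pairs`), `undefined_pairs` (`a`, `b`, `reason`)
#'   and `dropped_attributes`.
#' @export
build_clinical_network <- function(tbl, rho_min = 0.95, min_pairs = 20,
                                   use_abs = FALSE) {
  stopifnot(inherits(tbl, "binned_table"))
  attrs <- names(tbl$data)
  if (length(attrs) < 2) stop("need at least 2 attributes")
  usable <- vapply(attrs, function(a) {
    col <- tbl$data[[a]]
    sum(!is.na(col)) >= min_pairs && length(unique(col[!is.na(col)])) >= 2
  }, TRUE)
  if (any(!usable))
    message(sum(!usable), " attribute(s) dropped before correlation ",
            "(too few non-null entries or constant after binning)")
  attrs <- sort(attrs[usable])
  edges <- list(); undef <- list()
  if (length(attrs) >= 2) {
    pairs <- utils::combn(attrs, 2)
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      sp <- suppressMessages(
        spearman_pair(tbl$data[[a]], tbl$data[[b]], min_pairs = min_pairs))
      if (!sp$defined) {
        undef[[length(undef) + 1]] <-
          data.frame(a = a, b = b, reason = sp$reason,
                     stringsAsFactors = FALSE)
      } else if ((use_abs && abs(sp$rho) >= rho_min) ||
                 (!use_abs && sp$rho >= rho_min)) {
        edges[[length(edges) + 1]] <-
          data.frame(a = a, b = b, rho = sp$rho, n_pairs = sp$n_pairs,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), rho = numeric(),
               n_pairs = integer(), stringsAsFactors = FALSE)
  undef <- if (length(undef)) do.call(rbind, undef) else
    data.frame(a = character(), b = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(nodes = attrs, edges = edges, undefined_pairs = undef,
                 rho_min = rho_min, min_pairs = min_pairs,
                 dropped_attributes = names(usable)[!usable]),
            class = "clinical_network")
}

#' @export
print.clinical_network <- function(x, ...) {
  cat(sprintf("<clinical_network: %d attributes, %d edges (rho >= %.2f), %d undefined pairs>\n",
              length(x$nodes), nrow(x$edges), x$rho_min,
              nrow(x$undefined_pairs)))
  invisible(x)
}

network_degrees <- function(net) {
  stopifnot(inherits(net, "clinical_network"))
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$a); t2 <- table(net$edges$b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Log-log fit of the network degree distribution
#'
#' Builds a plain histogram with one bin per integer degree (nodes of degree
#' zero excluded), fits a least-squares line through the nonzero-count
#' `(log10 degree, log10 count)` points, and reports the slope, intercept
#' and the Pearson correlation of the fitted points. A strongly linear fit
#' (|R| near 1) is the usual operational signature of a scale-free network.
#'
#' @param net a [build_clinical_network()] result, or a pre-computed degree
#'   histogram as a data.frame with columns `degree` and `count`.
#' @return An object of class `degree_fit`: `histogram` (degree, count),
#'   `slope`, `intercept`, `fit_R`.
#' @export
degree_fit <- function(net) {
  if (is.data.frame(net)) {
    stopifnot(all(c("degree", "count") %in% names(net)))
    hist <- net[net$count > 0 & net$degree >= 1, c("degree", "count")]
  } else {
    deg <- network_degrees(net)
    deg <- deg[deg >= 1]
    if (!length(deg)) stop("no nodes with degree >= 1")
    h <- table(deg)
    hist <- data.frame(degree = as.integer(names(h)),
                       count = as.integer(h))
  }
  if (nrow(hist) < 2)
    stop("degree fit undefined: fewer than 2 distinct degrees")
  lx <- log10(hist$degree); ly <- log10(hist$count)
  fit <- stats::lm(ly ~ lx)
  structure(list(histogram = hist,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_R = stats::cor(lx, ly)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit: slope %.3f, intercept %.3f, R = %.3f over %d bins>\n",
              x$slope, x$intercept, x$fit_R, nrow(x$histogram)))
  invisible(x)
}

#' Highest-degree attributes of a clinical network
#'
#' @param net a [build_clinical_network()] result.
#' @param k number of attributes to return (default 10); requesting more
#'   than exist returns the full ranking with a message.
#' @return data.frame (`attribute`, `degree`) sorted by degree descending,
#'   ties broken lexicographically.
#' @export
top_hubs <- function(net, k = 10) {
  deg <- network_degrees(net)
  if (k > length(deg)) {
    message("k exceeds node count; returning the full ranking")
    k <- length(deg)
  }
  ord <- order(-deg, names(deg))
  out <- data.frame(attribute = names(deg)[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
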