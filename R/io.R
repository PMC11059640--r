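#' Copy-number profile matrix with bin annotations
#'
#' The observed data container: one row per cell, one column per genomic
#' bin, with per-bin coordinates (0-based, half-open).
#'
#' @param values Cells-by-bins numeric matrix, cell labels as row names; no
#'   negative values.
#' @param bins Data frame with columns `chrom`, `start`, `end`, one row per
#'   bin; bins must not overlap within a chromosome.
#' @return An object of class `cn_profiles`.
#' @export
cn_profiles <- function(values, bins = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("cells need unique row names", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("copy numbers must be non-negative", call. = FALSE)
  if (is.null(bins))
    bins <- tibble::tibble(chrom = "linear",
                           start = seq_len(ncol(values)) - 1L,
                           end = seq_len(ncol(values)))
  bins <- tibble::as_tibble(bins)
  if (!all(c("chrom", "start", "end") %in% names(bins)))
    stop("`bins` needs chrom, start, end columns", call. = FALSE)
  if (nrow(bins) != ncol(values))
    stop("one bin annotation row per matrix column required", call. = FALSE)
  for (cr in unique(bins$chrom)) {
    b <- bins[bins$chrom == cr, ]
    b <- b[order(b$start), ]
    if (any(b$end[-nrow(b)] > b$start[-1]))
      stop("overlapping bins on chromosome ", cr, call. = FALSE)
  }
  structure(list(values = values, bins = bins), class = "cn_profiles")
}

#' @export
print.cn_profiles <- function(x, ...) {
  cat("Copy-number profiles: ", nrow(x$values), " cells x ",
      ncol(x$values), " bins\n", sep = "")
  invisible(x)
}

#' @export
dim.cn_profiles <- function(x) dim(x$values)

file_header_lines <- function(seed = NULL, config = NULL) {
  v <- as.character(utils::packageVersion("cnphylo"))
  h <- if (is.null(config)) "none"
       else substr(rlang::hash(config), 1, 12)
  sprintf("# cnphylo %s seed=%s config_hash=%s coordinates=0-based-half-open",
          v, if (is.null(seed)) "NA" else seed, h)
}

#' Read a Ginkgo-style copy-number profile TSV
#'
#' Expects a tab-separated file with header columns `CHR`, `START`, `END`
#' followed by one column per cell; `#`-prefixed lines are ignored.
#' Coordinates are 0-based half-open. Non-numeric entries become missing.
#'
#' @param path File path.
#' @return A [cn_profiles()] object.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing profile file: ", path, call. = FALSE)
  hdr <- strsplit(readr::read_lines(path, n_max = 50), "\t")
  hdr <- hdr[!vapply(hdr, function(l) grepl("^#", l[1]), logical(1))][[1]]
  if (length(hdr) < 4 || !identical(toupper(hdr[1:3]), c("CHR", "START", "END")))
    stop("profile file must start with CHR, START, END columns followed by cells",
         call. = FALSE)
  cells <- hdr[-(1:3)]
  dup <- cells[duplicated(cells)]
  if (length(dup))
    stop("duplicated cell column(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          .default = readr::col_double(),
                          CHR = readr::col_character()))
  values <- t(as.matrix(df[, cells, drop = FALSE]))
  rownames(values) <- cells
  cn_profiles(values, tibble::tibble(chrom = df$CHR, start = df$START,
                                     end = df$END))
}

#' Write a Ginkgo-style copy-number profile TSV
#'
#' @param x A [cn_profiles()] object.
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "cn_profiles"))
  df <- tibble::tibble(CHR = x$bins$chrom, START = x$bins$start,
                       END = x$bins$end)
  vals <- tibble::as_tibble(t(x$values), .name_repair = "minimal")
  names(vals) <- rownames(x$values)
  readr::write_lines(file_header_lines(seed, config), path)
  readr::write_tsv(dplyr::bind_cols(df, vals), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# annotated Newick / NEXUS tree logs

# serialize a cn_tree to Newick with per-branch [&rate=...] metadata and a
# root [&d=...] annotation; labels may be substituted via `translate`
tree_to_newick <- function(tree, translate = NULL, digits = 12) {
  rates <- effective_rates(tree)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  ch <- tree_children(tree)
  rec <- function(v) {
    lab <- if (v <= tree$ntip) {
      l <- tree$tip_label[v]
      if (!is.null(translate)) as.character(translate[l]) else l
    } else ""
    body <- if (v > tree$ntip)
      paste0("(", rec(ch[[v]][1]), ",", rec(ch[[v]][2]), ")", lab)
    else lab
    if (v == tree$root) {
      paste0(body, "[&d=", fmt(tree$root_stem_d), "]:0")
    } else {
      len <- tree$height[tree$parent[v]] - tree$height[v]
      paste0(body, "[&rate=", fmt(rates[v]),
             ",on=", as.integer(tree$rate_on[v]),
             ",mult=", fmt(tree$rate_mult[v]), "]:", fmt(len))
    }
  }
  paste0(rec(tree$root), ";")
}

# tokenize + recursive-descent parse of annotated Newick; returns a cn_tree
parse_newick_tree <- function(text, translate = NULL) {
  text <- trimws(text)
  pos <- 1L
  nchar_t <- nchar(text)
  peek <- function() substr(text, pos, pos)
  fail <- function(msg) stop("Newick parse error at position ", pos, ": ",
                             msg, call. = FALSE)
  nodes <- list()   # list of list(children=, label=, length=, meta=)
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(children = integer(), label = "",
                                         length = NA_real_, meta = "")
    length(nodes)
  }
  read_label <- function() {
    start <- pos
    while (pos <= nchar_t && !(peek() %in% c(",", ")", "(", ":", ";", "[")))
      pos <<- pos + 1L
    substr(text, start, pos - 1L)
  }
  read_meta <- function() {
    if (peek() != "[") return("")
    start <- pos
    while (pos <= nchar_t && peek() != "]") pos <<- pos + 1L
    if (pos > nchar_t) fail("unterminated [ comment")
    pos <<- pos + 1L
    substr(text, start + 1L, pos - 2L)
  }
  parse_clade <- function() {
    id <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade()
        nodes[[id]]$children <<- c(nodes[[id]]$children, child)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      nodes[[id]]$label <<- read_label()
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a taxon label")
      nodes[[id]]$label <<- lab
    }
    nodes[[id]]$meta <<- read_meta()
    if (peek() == ":") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= nchar_t && grepl("[-0-9.eE+]", peek())) pos <<- pos + 1L
      nodes[[id]]$length <<- as.numeric(substr(text, start, pos - 1L))
    }
    id
  }
  root_id <- parse_clade()
  if (peek() != ";") fail("expected ';'")
  # assemble: tips in encounter order
  is_tip <- vapply(nodes, function(nd) length(nd$children) == 0L, logical(1))
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)
  n <- length(tip_ids)
  m <- 2L * n - 1L
  if (length(int_ids) != n - 1L)
    fail("tree is not binary")
  idx <- integer(length(nodes))
  idx[tip_ids] <- seq_len(n)
  idx[int_ids] <- n + seq_along(int_ids)
  parent <- integer(m)
  depth <- numeric(m)
  meta <- character(m)
  labels <- character(n)
  walk <- function(id, d) {
    v <- idx[id]
    depth[v] <<- d
    meta[v] <<- nodes[[id]]$meta
    if (idx[id] <= n) {
      lab <- nodes[[id]]$label
      if (!is.null(translate)) {
        tr <- translate[lab]
        if (!is.na(tr)) lab <- as.character(tr)
      }
      labels[v] <<- lab
    }
    for (cid in nodes[[id]]$children) {
      parent[idx[cid]] <<- v
      walk(cid, d + nodes[[cid]]$length)
    }
  }
  walk(root_id, 0)
  h <- max(depth) - depth
  h[abs(h) < 1e-9] <- 0
  meta_field <- function(s, key) {
    mm <- regmatches(s, regexec(paste0(key, "=([-0-9.eE+]+)"), s))[[1]]
    if (length(mm) == 2) as.numeric(mm[2]) else NA_real_
  }
  d <- meta_field(meta[idx[root_id]], "d")
  mult <- vapply(meta, meta_field, numeric(1), key = "mult")
  on <- vapply(meta, meta_field, numeric(1), key = "on")
  mult[is.na(mult)] <- 1
  on[is.na(on)] <- 0
  cn_tree(parent, h, labels,
          rate_mult = mult, rate_on = on > 0,
          root_stem_d = if (is.na(d)) 0.5 else d)
}

#' Write a NEXUS tree log
#'
#' Phylogenetics-standard NEXUS: a taxa block, a translate table, and one annotated
#' tree per sampled state with per-branch rate metadata in `[&...]`
#' comments.
#'
#' @param trees List of [cn_tree()] samples (or a single tree).
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tree_log <- function(trees, path, seed = NULL, config = NULL) {
  if (inherits(trees, "cn_tree")) trees <- list(trees)
  taxa <- trees[[1]]$tip_label
  translate <- stats::setNames(seq_along(taxa), taxa)
  lines <- c("#NEXUS",
             paste0("[", file_header_lines(seed, config), "]"),
             "begin taxa;",
             paste0("\tdimensions ntax=", length(taxa), ";"),
             "\ttaxlabels",
             paste0("\t\t", taxa),
             "\t\t;",
             "end;",
             "begin trees;",
             paste0("\ttranslate"),
             paste0("\t\t", seq_along(taxa), " ", taxa,
                    c(rep(",", length(taxa) - 1), "")),
             "\t\t;")
  body <- vapply(seq_along(trees), function(i)
    paste0("tree STATE_", i - 1L, " = [&R] ",
           tree_to_newick(trees[[i]], translate)), character(1))
  readr::write_lines(c(lines, body, "end;"), path)
  invisible(path)
}

#' Read a NEXUS tree log
#'
#' Parses the translate table and the annotated tree lines written by
#' [write_tree_log()] (per-branch rate metadata is recovered from the
#' `[&...]` comments).
#'
#' @param path File path.
#' @return List of [cn_tree()] objects.
#' @export
read_tree_log <- function(path) {
  lines <- readr::read_lines(path)
  if (!length(lines) || !grepl("^#NEXUS", lines[1], ignore.case = TRUE))
    stop("not a NEXUS file: ", path, call. = FALSE)
  # translate table: "<id> <label>[,;]"
  tr_start <- grep("^\\s*translate", lines, ignore.case = TRUE)
  translate <- NULL
  if (length(tr_start)) {
    i <- tr_start[1] + 1L
    pairs <- character()
    while (i <= length(lines) && !grepl("^\\s*;", lines[i])) {
      pairs <- c(pairs, lines[i])
      if (grepl(";\\s*$", lines[i])) break
      i <- i + 1L
    }
    pairs <- gsub("[,;]\\s*$", "", trimws(pairs))
    pairs <- pairs[nzchar(pairs)]
    sp <- strsplit(pairs, "\\s+")
    translate <- stats::setNames(vapply(sp, `[`, character(1), 2),
                                 vapply(sp, `[`, character(1), 1))
  }
  tree_lines <- grep("^\\s*tree\\s", lines, ignore.case = TRUE, value = TRUE)
  if (!length(tree_lines)) stop("no tree lines in ", path, call. = FALSE)
  purrr::map(tree_lines, function(l) {
    nwk <- sub("^[^=]*=\\s*(\\[&R\\]\\s*)?", "", l)
    parse_newick_tree(nwk, translate)
  })
}

#' Write the scalar MCMC trace as TSV
#'
#' @param fit A `cn_mcmc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  readr::write_lines(file_header_lines(fit$seed, fit$config), path)
  readr::write_tsv(fit$trace, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a simulated event list as BED-like TSV
#'
#' @param events A `cn_events` tibble.
#' @param path Output path.
#' @param seed Optional provenance.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, seed = NULL) {
  gl <- attr(events, "genome_length")
  df <- tibble::tibble(chrom = "linear",
                       start_bp = round(events$start * gl),
                       end_bp = round(pmin(events$start +
                                             events$length_bp / gl, 1) * gl),
                       branch = events$branch, allele = events$allele,
                       sign = ifelse(events$sign > 0, "gain", "loss"))
  readr::write_lines(c(file_header_lines(seed),
                       sprintf("# genome_length=%.0f", gl)), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write reconstructed profiles as TSV
#'
#' Node-by-bin states with the input's bin annotation columns; internal
#' nodes use the deterministic postorder labels also recorded in the output
#' tree.
#'
#' @param recon A `cn_reconstruction`.
#' @param bins Bin annotation tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @param seed Optional provenance.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(recon, bins, path, seed = NULL) {
  df <- tibble::tibble(CHR = bins$chrom, START = bins$start, END = bins$end)
  vals <- tibble::as_tibble(t(recon$states), .name_repair = "minimal")
  names(vals) <- rownames(recon$states)
  readr::write_lines(file_header_lines(seed), path)
  readr::write_tsv(dplyr::bind_cols(df, vals), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [mcmc_config()] and
#' [cn_priors()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An [mcmc_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML sequences arrive as lists; bounds etc. need numeric vectors
  raw <- lapply(raw, function(v)
    if (is.list(v) && all(vapply(v, is.numeric, logical(1)))) unlist(v) else v)
  prior_keys <- names(formals(cn_priors))
  cfg_keys <- setdiff(names(formals(mcmc_config)), "priors")
  bad <- setdiff(names(raw), c(prior_keys, cfg_keys))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  priors <- do.call(cn_priors, raw[intersect(names(raw), prior_keys)])
  do.call(mcmc_config,
          c(raw[intersect(names(raw), cfg_keys)], list(priors = priors)))
}
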