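# The four data-pairing modes, train/val splitting, deterministic-transform
# caching, and epoch-portion reloading for collections larger than memory.

#' Build a manifest of sample pairs from one of the four layout modes
#'
#' Modes: `csv_manifest` (a CSV with header columns naming source/target
#' and optional exclusion/weight paths), `paired_folders` (two folders,
#' records matched by identical file name), `suffix_convention` (one folder,
#' files `stem<source_suffix>.tif` / `stem<target_suffix>.tif` matched by
#' stem), `presplit_folders` (`train/` and `val/` subtrees, each in
#' paired-folders layout, assigning the split directly).  The other modes
#' split records into train/val by `val_fraction` using the run seed.
#' Record order is deterministic (lexicographic by source reference).
#'
#' @param cfg `data` section of a run config.
#' @param seed run seed controlling the random split.
#' @return list of class `im2im_manifest`: `records` (each a list with
#'   `id`, `source`, `target`, `exclusion`, `weight`, `split`), `mode`,
#'   `root`.
#' @export
build_manifest <- function(cfg, seed = 42L) {
  mode <- cfg$mode
  root <- cfg$data_path
  if (!nzchar(root) || !file.exists(root))
    stop("data path does not exist: '", root, "'")
  tif <- function(dir) sort(list.files(dir, pattern = "\\.tiff?$",
                                       full.names = FALSE))
  rec <- function(id, source, target = NULL, exclusion = NULL,
                  weight = NULL, split = "unassigned")
    list(id = id, source = source, target = target, exclusion = exclusion,
         weight = weight, split = split)
  records <- list()
  if (mode == "csv_manifest") {
    csv <- if (dir.exists(root)) file.path(root, "manifest.csv") else root
    if (!file.exists(csv)) stop("csv manifest not found: ", csv)
    tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
    if (!cfg$source_key %in% names(tab))
      stop("csv manifest lacks source column '", cfg$source_key, "'")
    if (!cfg$target_key %in% names(tab))
      stop("csv manifest lacks target column '", cfg$target_key, "'")
    base <- dirname(csv)
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    for (i in seq_len(nrow(tab))) {
      s <- resolve(tab[[cfg$source_key]][i])
      t <- resolve(tab[[cfg$target_key]][i])
      for (p in c(s, t)) if (!file.exists(p))
        stop("csv manifest row ", i, ": file not found: ", p)
      ex <- NULL
      if (cfg$exclusion_key %in% names(tab) &&
          nzchar(tab[[cfg$exclusion_key]][i])) {
        ex <- resolve(tab[[cfg$exclusion_key]][i])
        if (!file.exists(ex))
          stop("csv manifest row ", i, ": file not found: ", ex)
      }
      wt <- NULL
      if (cfg$weight_key %in% names(tab) &&
          nzchar(tab[[cfg$weight_key]][i])) {
        wt <- resolve(tab[[cfg$weight_key]][i])
        if (!file.exists(wt))
          stop("csv manifest row ", i, ": file not found: ", wt)
      }
      records[[length(records) + 1L]] <-
        rec(basename(s), s, t, ex, wt)
    }
  } else if (mode == "paired_folders") {
    sdir <- file.path(root, cfg$source_folder)
    tdir <- file.path(root, cfg$target_folder)
    sf <- tif(sdir); tf <- tif(tdir)
    orphans <- c(setdiff(sf, tf), setdiff(tf, sf))
    if (length(orphans))
      stop("unmatched files between '", cfg$source_folder, "' and '",
           cfg$target_folder, "': ", paste(orphans, collapse = ", "))
    for (f in sf)
      records[[length(records) + 1L]] <-
        rec(f, file.path(sdir, f), file.path(tdir, f))
  } else if (mode == "suffix_convention") {
    fs <- tif(root)
    stem_of <- function(f, suf) {
      b <- sub("\\.tiff?$", "", f)
      ifelse(endsWith(b, suf), substr(b, 1, nchar(b) - nchar(suf)), NA)
    }
    src <- fs[!is.na(stem_of(fs, cfg$source_suffix))]
    tgt <- fs[!is.na(stem_of(fs, cfg$target_suffix))]
    ss <- vapply(src, stem_of, "", suf = cfg$source_suffix)
    ts <- vapply(tgt, stem_of, "", suf = cfg$target_suffix)
    orphans <- c(setdiff(ss, ts), setdiff(ts, ss))
    if (length(orphans))
      stop("orphan stems without a matched pair: ",
           paste(sort(unique(orphans)), collapse = ", "))
    o <- order(ss)
    for (i in o)
      records[[length(records) + 1L]] <-
        rec(ss[i], file.path(root, src[i]),
            file.path(root, tgt[match(ss[i], ts)]))
  } else if (mode == "presplit_folders") {
    for (split in c("train", "val")) {
      sdir <- file.path(root, split, cfg$source_folder)
      tdir <- file.path(root, split, cfg$target_folder)
      if (!dir.exists(sdir)) next
      sf <- tif(sdir); tf <- tif(tdir)
      orphans <- c(setdiff(sf, tf), setdiff(tf, sf))
      if (length(orphans))
        stop("unmatched files under ", split, "/: ",
             paste(orphans, collapse = ", "))
      for (f in sf)
        records[[length(records) + 1L]] <-
          rec(paste0(split, "/", f), file.path(sdir, f),
              file.path(tdir, f), split = split)
    }
  } else stop("unknown data mode: ", mode)
  if (!length(records)) stop("empty manifest under ", root)
  ord <- order(vapply(records, `[[`, "", "source"))
  records <- records[ord]
  if (mode != "presplit_folders") {
    n <- length(records)
    nval <- floor(cfg$val_fraction * n)
    if (n - nval < 1) stop("val_fraction leaves no training records")
    st <- rng_stream(child_seed(seed, "split"))
    vidx <- if (nval > 0) with_rng(st, sample.int(n, nval)) else integer(0)
    for (i in seq_len(n))
      records[[i]]$split <- if (i %in% vidx) "val" else "train"
  }
  structure(list(records = records, mode = mode, root = root),
            class = "im2im_manifest")
}

#' @export
print.im2im_manifest <- function(x, ...) {
  splits <- table(vapply(x$records, `[[`, "", "split"))
  cat("<im2im_manifest> mode=", x$mode, " n=", length(x$records), " [",
      paste(names(splits), splits, sep = ":", collapse = " "), "]\n",
      sep = "")
  invisible(x)
}

#' Records of one split
#' @param manifest an `im2im_manifest`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list of records.
#' @export
manifest_split <- function(manifest, split)
  Filter(function(r) identical(r$split, split), manifest$records)

#' Dataset with cached deterministic transforms
#'
#' The first access to a record applies the deterministic transform list
#' (normalization, padding) and persists the result under a key derived
#' from the file path, its modification time and the serialized transform
#' spec; later accesses load from the cache.  Changing any transform
#' parameter changes the key and forces recomputation.
#'
#' @param manifest an `im2im_manifest`.
#' @param transforms ordered transform list (each entry must be flagged
#'   `deterministic`).
#' @param cache_dir cache directory (created if missing).
#' @return list of class `im2im_dataset` with `get(i)` returning
#'   `list(source, target, exclusion, weight)` arrays and a
#'   `stats` environment counting transform applications.
#' @export
cached_dataset <- function(manifest, transforms = list(), cache_dir = NULL) {
  for (tr in transforms)
    if (!isTRUE(tr$deterministic))
      stop("cached_dataset accepts only deterministic transforms; '",
           tr$name, "' is not flagged deterministic")
  if (is.null(cache_dir) || !nzchar(cache_dir))
    cache_dir <- file.path(tempdir(), "im2im_cache")
  ok <- dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cache_dir)) stop("cache_dir not writable: ", cache_dir)
  stats <- new.env(); stats$transform_calls <- 0L
  load_one <- function(ref, apply_tr) {
    if (is.null(ref)) return(NULL)
    img <- read_image(ref)
    # "auto": intensity (float) targets are normalized like sources;
    # integer label/mask targets are left untouched
    if (identical(apply_tr, "auto")) apply_tr <- img$dtype_kind == "float"
    if (isTRUE(apply_tr)) for (tr in transforms) {
      img <- apply_transform(img, tr)
      stats$transform_calls <- stats$transform_calls + 1L
    }
    img
  }
  get <- function(i) {
    r <- manifest$records[[i]]
    key <- spec_digest(list(src = r$source, mtime =
                              as.numeric(file.mtime(r$source)),
                            transforms = transforms))
    f <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(f)) return(readRDS(f))
    out <- list(source = load_one(r$source, TRUE),
                target = load_one(r$target, "auto"),
                exclusion = load_one(r$exclusion, FALSE),
                weight = load_one(r$weight, FALSE),
                id = r$id)
    saveRDS(out, f)
    out
  }
  structure(list(get = get, n = length(manifest$records),
                 manifest = manifest, stats = stats,
                 cache_dir = cache_dir),
            class = "im2im_dataset")
}

#' Epoch-portion loader
#'
#' Yields, for each reload period, `ceiling(portion_fraction * N)` record
#' indices drawn without replacement by walking a seeded permutation;
#' successive periods continue the permutation (topping up from a fresh
#' permutation arranged to avoid immediate repeats), so every record is
#' visited before any repeats — full coverage over
#' `ceiling(1 / portion_fraction)` periods.
#'
#' @param n number of records (or an `im2im_dataset`).
#' @param portion_fraction fraction in `(0, 1]` loaded per period.
#' @param reload_every reload cadence in epochs.
#' @param seed integer seed.
#' @return function `(epoch) -> integer indices`, deterministic in
#'   `(seed, epoch)`.
#' @export
portion_loader <- function(n, portion_fraction = 1, reload_every = 1L,
                           seed = 42L) {
  if (inherits(n, "im2im_dataset")) n <- n$n
  stopifnot(portion_fraction > 0, portion_fraction <= 1)
  m <- ceiling(portion_fraction * n)
  if (m < 1) stop("portion too small: no records per epoch")
  st <- rng_stream(child_seed(seed, "portion"))
  stream <- with_rng(st, sample.int(n))
  fetch_upto <- function(k) {
    while (length(stream) < k) {
      nxt <- with_rng(st, sample.int(n))
      # avoid repeats straddling the permutation boundary within one period
      tail_taken <- stream[max(1, length(stream) - m + 2):length(stream)]
      bad <- which(nxt[seq_len(min(m, n))] %in% tail_taken)
      for (b in bad) {
        swap <- which(!nxt %in% tail_taken)
        swap <- swap[swap > min(m, n)]
        if (length(swap)) {
          tmp <- nxt[b]; nxt[b] <- nxt[swap[1]]; nxt[swap[1]] <- tmp
        }
      }
      stream <<- c(stream, nxt)
    }
  }
  chunks <- list()
  function(epoch) {
    period <- (epoch - 1L) %/% reload_every + 1L
    while (length(chunks) < period) {
      k <- length(chunks)
      fetch_upto((k + 1L) * m)
      chunks[[k + 1L]] <<- stream[k * m + seq_len(m)]
    }
    chunks[[period]]
  }
}
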