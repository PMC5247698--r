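# Shared fixtures: small fields keep unit tests fast; acceptance tests use
# the protocol-sized 512 px fields.

small_field_spec <- function(fat = 0.1, seed = 1L, ...) {
  field_spec(width_px = 256L, height_px = 256L, um_per_px = 0.5,
             target_fat_fraction = fat, seed = seed, ...)
}

# O(n^2) concordance-probability oracle for AUROC:
# P(score+ > score-) + 0.5 P(score+ == score-)
concordance_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# All permutations of a vector (used for exact Spearman enumeration).
all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)))
}

# A minimal hand-built segmentation result, for aggregation arithmetic.
fake_seg_result <- function(fat, parenchyma, id = "fake") {
  structure(list(fat_mask = NULL, parenchyma_mask = NULL,
                 exclusion_mask = NULL, background_mask = NULL,
                 fat_area_um2 = fat, parenchyma_area_um2 = parenchyma,
                 fraction = if (parenchyma > 0) fat / parenchyma else NA_real_,
                 field_id = id),
            class = "segmentation_result")
}
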