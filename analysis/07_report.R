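#!/usr/bin/env Rscript
# Headline report: the end-to-end pipeline on both groups, emitting the
# summary table (group, n, R/theta, delta, nu, r/m, pseudogenes, omega) and
# the figure-shaped TSVs, plus simple figures.

source("analysis/00_config.R")

outdir <- file.path(RESULTS_DIR, "report")
res <- run_pipeline(study_configs(), outdir = outdir)

print(res$summary, digits = 3)
for (nm in names(res$tests)) {
  t <- res$tests[[nm]]
  if (inherits(t, "group_comparison")) { cat(nm, ": "); print(t) }
}

# figures (scatter of omega vs pseudogene load with per-group regressions,
# and the per-branch import-count histogram)
figdir <- file.path(RESULTS_DIR, "figures")
dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
suppressMessages(library(ggplot2))

pts <- do.call(rbind, lapply(names(res$analyses), function(g) {
  a <- res$analyses[[g]]
  ids <- rownames(a$alignment)
  cnt <- as.integer(table(factor(a$pseudogenes$genome_id, levels = ids)))
  tips <- a$branch_omega[a$branch_omega$is_tip, ]
  data.frame(group = g, genome = ids, omega = tips$omega[match(ids, tips$branch)],
             pseudogenes = cnt)
}))
p1 <- ggplot(pts, aes(omega, pseudogenes, colour = group)) +
  geom_point(size = 2) +
  geom_smooth(method = "lm", se = FALSE, linewidth = 0.5) +
  geom_smooth(aes(group = 1), method = "lm", se = FALSE,
              colour = "grey40", linetype = 2, linewidth = 0.5) +
  labs(x = "dN/dS (terminal branch)", y = "pseudogenes per genome") +
  theme_minimal()
ggsave(file.path(figdir, "omega_vs_pseudogenes.pdf"), p1, width = 5, height = 4)

imp <- do.call(rbind, lapply(names(res$analyses), function(g) {
  a <- res$analyses[[g]]
  seg <- a$imports
  data.frame(group = g, branch = a$recomb$per_branch$branch,
             n_imports = as.integer(table(factor(seg$branch,
                                                 levels = a$recomb$per_branch$branch))))
}))
p2 <- ggplot(imp, aes(branch, n_imports, fill = group)) +
  geom_col() + facet_wrap(~group, scales = "free_x") +
  labs(x = NULL, y = "import segments per branch") +
  theme_minimal() + theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
ggsave(file.path(figdir, "import_counts.pdf"), p2, width = 8, height = 4)

message("report written under ", outdir, "; figures under ", figdir)
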