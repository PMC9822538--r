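#' Run the scaled simulation study end to end
#'
#' Simulates a diploid contig with planted SNPs/short indels and
#' low-coverage error-perturbed long reads, trains both genotyper
#' networks on the left part of the contig, runs the full two-round
#' calling pipeline, and evaluates the final and per-model call sets on
#' the held-out right part. Default conditions: 200 kb contig, SNP
#' density 1/kb (two-thirds heterozygous), indel density 0.2/kb, 16x
#' coverage, 4% substitution + 1% insertion + 1% deletion error.
#'
#' @param seed integer; drives genome (`seed`), reads (`seed + 1`) and
#'   training (`seed + 2`).
#' @param length contig length in bases.
#' @param coverage mean read depth.
#' @param error_model per-base error rates (list `sub`, `ins`, `del`).
#' @param snp_rate,het_fraction,indel_rate genome variant densities.
#' @param train_frac fraction of the contig used for training; the rest
#'   is the held-out evaluation region.
#' @param config a [snp_call_config()].
#' @param vcf_path optional path for the final VCF.
#' @return list with `genome`, `reads`, `models`, `results` (the
#'   [call_snps()] output) and `metrics`: precision/recall/F1 of the
#'   merged calls and of each round's thresholded calls on the held-out
#'   region, candidate/call counts, and haplotagging accuracy against
#'   the simulator truth.
#' @export
run_simulation_study <- function(seed = 1L, length = 200000L, coverage = 16,
                                 error_model = list(sub = 0.04, ins = 0.01,
                                                    del = 0.01),
                                 snp_rate = 1e-3, het_fraction = 2/3,
                                 indel_rate = 2e-4, train_frac = 0.75,
                                 config = snp_call_config("desk"),
                                 vcf_path = NULL) {
  seed <- as.integer(seed)
  genome <- generate_diploid(length, snp_rate = snp_rate,
                             het_fraction = het_fraction,
                             indel_rate = indel_rate, seed = seed)
  reads <- simulate_reads(genome, coverage, error_model, seed = seed + 1L)
  split_at <- as.integer(length * train_frac)
  models <- train_snp_models(reads, genome, config, seed = seed + 2L,
                             region = c(0L, split_at))
  results <- call_snps(reads, genome, models$pileup_model, models$hap_model,
                       config, vcf_path = vcf_path)
  heldout <- data.frame(start = split_at, end = length)
  ev_final <- classify_against_truth(results$final, genome$truth_variants,
                                     heldout)
  ev_pile <- classify_against_truth(
    model_calls(results$calls_round1, config$delta),
    genome$truth_variants, heldout)
  ev_hap <- classify_against_truth(
    model_calls(results$calls_round2, config$delta),
    genome$truth_variants, heldout)
  tags <- results$haplotags
  tagged <- tags > 0L
  tag_acc <- if (any(tagged)) {
    agree <- mean((tags == reads$reads$truth_hap)[tagged])
    max(agree, 1 - agree)                 # global hap labelling is arbitrary
  } else NA_real_
  list(genome = genome, reads = reads, models = models, results = results,
       metrics = list(
         final = ev_final, pileup_model = ev_pile, haplotype_model = ev_hap,
         heldout_truth_snps = with(genome$truth_variants,
                                   sum(class == "SNP" & pos0 >= split_at)),
         candidates = nrow(results$candidates),
         final_calls = nrow(results$final),
         het_sites = results$counts$het_sites,
         haplotag_rate = mean(tagged),
         haplotag_accuracy = tag_acc))
}
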