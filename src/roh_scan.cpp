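#include <Rcpp.h>
using namespace Rcpp;

// Left-to-right maximal-run scanner for runs of homozygosity on a single
// chromosome. Genotypes are alternate-allele counts with -1 for missing.
// A run must start and end on a homozygous non-missing SNP, contain at most
// max_het heterozygotes and max_missing missing calls, have no internal
// inter-SNP gap above max_gap_bp, and meet the min_snps / min_length_bp
// floors (length = end_bp - start_bp, no +1). Runs are emitted as the
// leftmost maximal non-overlapping set: a window is grown until the next
// SNP would violate a budget or gap; the candidate is trimmed to homozygous
// endpoints; if it passes the floors it is emitted and scanning resumes
// after its end, otherwise scanning resumes after the first heterozygous or
// missing call inside the window (or after the breaking gap).
// [[Rcpp::export(name = ".scan_roh_chrom")]]
DataFrame scan_roh_chrom(IntegerMatrix geno, IntegerVector pos,
                         double min_length_bp, int min_snps,
                         int max_het, int max_missing, double max_gap_bp) {
  int n = geno.nrow();
  int m = geno.ncol();
  std::vector<int> out_sample, out_start, out_end, out_nsnp, out_het, out_miss;

  for (int s = 0; s < n; ++s) {
    int cursor = 0;
    while (cursor < m) {
      // advance to a homozygous non-missing start
      while (cursor < m) {
        int g = geno(s, cursor);
        if (g == 0 || g == 2) break;
        ++cursor;
      }
      if (cursor >= m) break;

      // grow the window greedily
      int j = cursor;
      int het = 0, miss = 0;
      int first_event = -1;       // first het or missing inside the window
      bool gap_break = false;
      int gap_right = -1;
      int closing = -1;           // SNP whose inclusion would burst a budget
      while (true) {
        int nxt = j + 1;
        if (nxt >= m) break;
        if ((double)pos[nxt] - (double)pos[j] > max_gap_bp) {
          gap_break = true;
          gap_right = nxt;
          break;
        }
        int g = geno(s, nxt);
        if (g == 1) {
          if (het + 1 > max_het) { closing = nxt; break; }
          ++het;
          if (first_event < 0) first_event = nxt;
        } else if (g < 0) {
          if (miss + 1 > max_missing) { closing = nxt; break; }
          ++miss;
          if (first_event < 0) first_event = nxt;
        }
        j = nxt;
      }

      // trim trailing het/missing so the run ends on a homozygote
      int e = j;
      while (e > cursor) {
        int g = geno(s, e);
        if (g == 0 || g == 2) break;
        --e;
      }
      int nsnp = e - cursor + 1;
      int het_in = 0, miss_in = 0;
      for (int t = cursor; t <= e; ++t) {
        int g = geno(s, t);
        if (g == 1) ++het_in;
        else if (g < 0) ++miss_in;
      }
      double len = (double)pos[e] - (double)pos[cursor];

      if (nsnp >= min_snps && len >= min_length_bp) {
        out_sample.push_back(s + 1);
        out_start.push_back(cursor + 1);
        out_end.push_back(e + 1);
        out_nsnp.push_back(nsnp);
        out_het.push_back(het_in);
        out_miss.push_back(miss_in);
        cursor = e + 1;
      } else if (first_event >= 0) {
        cursor = first_event + 1;
      } else if (gap_break) {
        cursor = gap_right;
      } else if (closing >= 0) {
        cursor = closing + 1;
      } else {
        cursor = j + 1;  // window reached the chromosome end
      }
    }
  }

  return DataFrame::create(
    _["sample"] = out_sample,
    _["start_idx"] = out_start,
    _["end_idx"] = out_end,
    _["n_snps"] = out_nsnp,
    _["n_het"] = out_het,
    _["n_missing"] = out_miss);
}
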