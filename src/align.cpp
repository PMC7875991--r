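#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sense-strand placement of each read at every start position of
// every hairpin.
//
// For each placement the in-template positions are split into a leading
// contiguous mismatch run (candidate 5' nontemplated addition), a trailing
// contiguous mismatch run (candidate 3' nontemplated addition), and the
// core between them. A placement is reported when:
//   core mismatches <= max_mismatch   (the bowtie -v style residual cap)
//   leading run     <= max_tail
//   trailing run    <= max_tail
//   3' overhang     <= max_overhang   (no template there; never a mismatch)
//   core length     >= min_core
// Terminal mismatch runs are exempt from the mismatch cap because they are
// exactly what end-modification calling classifies as nontemplated tails;
// a plain cap would make fully nontemplated 3-nt tails unmappable.
//
// max_mismatch = max_overhang = max_tail = 0 gives the strict
// (exact, full-length) mapper.
//
// Returns a data.frame with 1-based read index, hairpin index and start.
// [[Rcpp::export]]
DataFrame align_ungapped_all(CharacterVector reads, CharacterVector hairpins,
                             int max_mismatch, int max_overhang,
                             int max_tail, int min_core) {
  std::vector<int> out_read, out_hp, out_start, out_mm, out_core,
      out_run5, out_run3, out_over;
  int n_hp = hairpins.size();
  std::vector<std::string> hp(n_hp);
  for (int h = 0; h < n_hp; ++h) hp[h] = as<std::string>(hairpins[h]);

  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int L = rd.size();
    for (int h = 0; h < n_hp; ++h) {
      int hl = hp[h].size();
      int max_start = hl + max_overhang - L;
      for (int s = 0; s <= max_start; ++s) {
        int over = (s + L > hl) ? (s + L - hl) : 0;
        int in_bounds = L - over;
        if (in_bounds < min_core) continue;
        int run5 = 0;
        while (run5 < in_bounds && rd[run5] != hp[h][s + run5]) ++run5;
        if (run5 > max_tail) continue;
        int run3 = 0;
        while (run3 < in_bounds - run5 &&
               rd[in_bounds - 1 - run3] != hp[h][s + in_bounds - 1 - run3])
          ++run3;
        if (run3 > max_tail) continue;
        int core_len = in_bounds - run5 - run3;
        if (core_len < min_core) continue;
        int core_mm = 0;
        bool ok = true;
        for (int j = run5; j < in_bounds - run3; ++j) {
          if (rd[j] != hp[h][s + j]) {
            if (++core_mm > max_mismatch) { ok = false; break; }
          }
        }
        if (!ok) continue;
        out_read.push_back(r + 1);
        out_hp.push_back(h + 1);
        out_start.push_back(s + 1);
        out_mm.push_back(core_mm + run5 + run3);
        out_core.push_back(core_mm);
        out_run5.push_back(run5);
        out_run3.push_back(run3);
        out_over.push_back(over);
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["hairpin"] = out_hp,
                           _["start"] = out_start, _["mismatches"] = out_mm,
                           _["core_mismatches"] = out_core,
                           _["run5"] = out_run5, _["run3"] = out_run3,
                           _["overhang"] = out_over);
}
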