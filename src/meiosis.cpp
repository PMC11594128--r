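#include <Rcpp.h>
using namespace Rcpp;

// One gamete from a diploid parent: copy marker intervals from the two
// parental haplotype rows, switching at crossover points. Crossover count per
// chromosome is Poisson(genetic length in Morgans), positions uniform on the
// chromosome's cM span (no interference). Uses R's RNG so results are
// reproducible under set.seed().
static void make_gamete(const IntegerMatrix &haps, int row_a, int row_b,
                        const std::vector<int> &chr_start,
                        const std::vector<int> &chr_end,
                        const NumericVector &pos_cm,
                        IntegerMatrix &out, int out_row) {
  int n_chr = chr_start.size();
  for (int c = 0; c < n_chr; ++c) {
    int s = chr_start[c], e = chr_end[c]; // [s, e)
    double lo = pos_cm[s], hi = pos_cm[e - 1];
    double len_m = (hi - lo) / 100.0;
    int k = (len_m > 0.0) ? (int)R::rpois(len_m) : 0;
    int cur = (unif_rand() < 0.5) ? row_a : row_b;
    int oth = (cur == row_a) ? row_b : row_a;
    if (k == 0) {
      for (int j = s; j < e; ++j) out(out_row, j) = haps(cur, j);
      continue;
    }
    std::vector<double> xo(k);
    for (int i = 0; i < k; ++i) xo[i] = lo + unif_rand() * (hi - lo);
    std::sort(xo.begin(), xo.end());
    int xi = 0;
    for (int j = s; j < e; ++j) {
      while (xi < k && xo[xi] < pos_cm[j]) {
        std::swap(cur, oth);
        ++xi;
      }
      out(out_row, j) = haps(cur, j);
    }
  }
}

// One round of random mating producing n_out offspring (2*n_out gamete rows)
// from the diploid population in `haps`. Used when a derived panel is larger
// than the breeding population that produced it.
// [[Rcpp::export]]
IntegerMatrix offspring_cpp(IntegerMatrix haps, IntegerVector chrom,
                            NumericVector pos_cm, int n_out) {
  int n_hap = haps.nrow(), m = haps.ncol();
  if (n_hap % 2 != 0) stop("haplotype count must be even");
  int n_ind = n_hap / 2;
  std::vector<int> chr_start, chr_end;
  for (int j = 0; j < m; ++j) {
    if (j == 0 || chrom[j] != chrom[j - 1]) chr_start.push_back(j);
  }
  for (size_t c = 1; c < chr_start.size(); ++c) chr_end.push_back(chr_start[c]);
  chr_end.push_back(m);
  IntegerMatrix out(2 * n_out, m);
  for (int i = 0; i < n_out; ++i) {
    int sire = (int)(unif_rand() * n_ind);
    if (sire == n_ind) sire = n_ind - 1;
    int dam = (int)(unif_rand() * n_ind);
    if (dam == n_ind) dam = n_ind - 1;
    make_gamete(haps, 2 * sire, 2 * sire + 1, chr_start, chr_end, pos_cm,
                out, 2 * i);
    make_gamete(haps, 2 * dam, 2 * dam + 1, chr_start, chr_end, pos_cm,
                out, 2 * i + 1);
  }
  return out;
}

// Wright-Fisher random mating for n_gen discrete generations. `haps` holds a
// population of N = nrow/2 diploids (rows 2i, 2i+1 are individual i). Each
// generation draws, for every offspring, a sire and a dam uniformly with
// replacement (selfing allowed) and one recombinant gamete from each.
// With mig_rate > 0, each parent is instead drawn from the static `outgroup`
// diploid pool with that probability (continent-island migration).
// [[Rcpp::export]]
IntegerMatrix wf_generations_cpp(IntegerMatrix haps, IntegerVector chrom,
                                 NumericVector pos_cm, int n_gen,
                                 IntegerMatrix outgroup, double mig_rate) {
  int n_hap = haps.nrow(), m = haps.ncol();
  if (n_hap % 2 != 0) stop("haplotype count must be even");
  int n_ind = n_hap / 2;
  int n_out_ind = outgroup.nrow() / 2;
  if (mig_rate > 0 && n_out_ind == 0) stop("migration needs an outgroup pool");

  std::vector<int> chr_start, chr_end;
  for (int j = 0; j < m; ++j) {
    if (j == 0 || chrom[j] != chrom[j - 1]) chr_start.push_back(j);
  }
  for (size_t c = 1; c < chr_start.size(); ++c) chr_end.push_back(chr_start[c]);
  chr_end.push_back(m);

  IntegerMatrix cur = clone(haps);
  for (int g = 0; g < n_gen; ++g) {
    IntegerMatrix nxt(n_hap, m);
    for (int i = 0; i < n_ind; ++i) {
      for (int par = 0; par < 2; ++par) {
        bool migrant = (mig_rate > 0) && (unif_rand() < mig_rate);
        int pool_n = migrant ? n_out_ind : n_ind;
        int pick = (int)(unif_rand() * pool_n);
        if (pick == pool_n) pick = pool_n - 1;
        if (migrant) {
          make_gamete(outgroup, 2 * pick, 2 * pick + 1, chr_start, chr_end,
                      pos_cm, nxt, 2 * i + par);
        } else {
          make_gamete(cur, 2 * pick, 2 * pick + 1, chr_start, chr_end,
                      pos_cm, nxt, 2 * i + par);
        }
      }
    }
    cur = nxt;
  }
  return cur;
}
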