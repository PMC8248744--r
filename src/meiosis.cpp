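#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Haplotypes are raw (1-byte) matrices of 0/1 alleles, sites x individuals,
// with sites grouped by chromosome (chrom_offset/chrom_nsites give the row
// span of each chromosome).  Female meiosis performs exactly one crossover
// per chromosome at a uniform bp position.

static inline int sample_int(int n) {
  // uniform on 0..n-1 via the R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Breakpoint row count for one chromosome: number of sites with pos < bp.
static inline int brk_count(const int* pos, int ns, double bp) {
  return (int)(std::upper_bound(pos, pos + ns, bp,
                                [](double v, int p) { return v < (double)p; }) -
               pos);
}

struct GametePlan {
  int mother;
  std::vector<int> brk;     // per chromosome: rows taken from the first hap
  std::vector<bool> first;  // per chromosome: start on h1?
};

// Allele the planned gamete carries at global site row i (0-based).
static inline Rbyte plan_allele(const GametePlan& g, const RawMatrix& h1,
                                const RawMatrix& h2, int chrom_of_site,
                                int row_in_chrom, int i) {
  bool from_first = row_in_chrom < g.brk[chrom_of_site];
  bool use_h1 = g.first[chrom_of_site] ? from_first : !from_first;
  return use_h1 ? h1(i, g.mother) : h2(i, g.mother);
}

static void materialize(const GametePlan& g, const RawMatrix& h1,
                        const RawMatrix& h2, const IntegerVector& chrom_offset,
                        const IntegerVector& chrom_nsites, Rbyte* out) {
  int n_chrom = chrom_offset.size();
  for (int c = 0; c < n_chrom; ++c) {
    int off = chrom_offset[c], ns = chrom_nsites[c];
    int k = g.brk[c];
    const Rbyte* a = g.first[c] ? &h1(off, g.mother) : &h2(off, g.mother);
    const Rbyte* b = g.first[c] ? &h2(off, g.mother) : &h1(off, g.mother);
    std::copy(a, a + k, out + off);
    std::copy(b + k, b + ns, out + off + k);
  }
}

// One full haplodiploid generation: daughters = recombinant maternal gamete
// + random male's haplotype; sons = recombinant maternal gamete.  When loci
// are supplied, offspring survive viability selection with fitness
// multiplicative over loci: female_w(dose, locus) indexed by the diploid
// dose of the focal allele (0/1/2), male_w(allele, locus) by the haploid
// allele; sampling continues until the census is refilled, erroring out if
// fitness is effectively zero.
// [[Rcpp::export(name = ".advance_pop")]]
List advance_pop(const RawMatrix& fh1, const RawMatrix& fh2,
                 const RawMatrix& mh,
                 const IntegerVector& pos,
                 const IntegerVector& chrom_offset,
                 const IntegerVector& chrom_nsites,
                 const NumericVector& chrom_len,
                 const IntegerVector& causal_idx,
                 const NumericMatrix& female_w,  // 3 x n_loci: fitness by dose
                 const NumericMatrix& male_w,    // 2 x n_loci: fitness by allele
                 int n_females_out, int n_males_out) {
  const int n_sites = fh1.nrow();
  const int n_mothers = fh1.ncol();
  const int n_fathers = mh.ncol();
  const int n_chrom = chrom_offset.size();
  const int n_causal = causal_idx.size();
  const bool select = n_causal > 0;
  if (n_causal && (female_w.ncol() != n_causal || male_w.ncol() != n_causal))
    stop("fitness matrices must have one column per locus");
  if (n_mothers == 0 || n_fathers == 0) stop("empty population");

  std::vector<int> causal_chrom(n_causal), causal_row(n_causal);
  for (int k = 0; k < n_causal; ++k) {
    int i = causal_idx[k];
    if (i < 0 || i >= n_sites) stop("causal site index out of range");
    int c = 0;
    while (c + 1 < n_chrom && i >= chrom_offset[c + 1]) ++c;
    causal_chrom[k] = c;
    causal_row[k] = i - chrom_offset[c];
  }

  // every element is written below, so skip the zero-fill
  RawMatrix d_h1(no_init(n_sites, n_females_out));
  RawMatrix d_h2(no_init(n_sites, n_females_out));
  RawMatrix s_h(no_init(n_sites, n_males_out));
  RNGScope rng;

  GametePlan g;
  g.brk.resize(n_chrom);
  g.first.resize(n_chrom);
  auto plan = [&]() {
    g.mother = sample_int(n_mothers);
    for (int c = 0; c < n_chrom; ++c) {
      double bp = unif_rand() * chrom_len[c];
      g.brk[c] = brk_count(&pos[chrom_offset[c]], chrom_nsites[c], bp);
      g.first[c] = unif_rand() < 0.5;
    }
  };

  const long max_attempts = 1000L * (n_females_out + n_males_out) + 1000L;
  long attempts = 0;

  for (int d = 0; d < n_females_out; ) {
    if (++attempts > max_attempts)
      stop("population extinct after selection (fitness too low)");
    plan();
    int father = sample_int(n_fathers);
    if (select) {
      double w = 1.0;
      for (int k = 0; k < n_causal; ++k) {
        int i = causal_idx[k];
        int dose = (int)plan_allele(g, fh1, fh2, causal_chrom[k],
                                    causal_row[k], i) +
                   (int)mh(i, father);
        w *= female_w(dose, k);
      }
      if (unif_rand() >= w) continue;
    }
    materialize(g, fh1, fh2, chrom_offset, chrom_nsites, &d_h1(0, d));
    std::copy(&mh(0, father), &mh(0, father) + n_sites, &d_h2(0, d));
    ++d;
  }

  for (int s = 0; s < n_males_out; ) {
    if (++attempts > max_attempts)
      stop("population extinct after selection (fitness too low)");
    plan();
    if (select) {
      double w = 1.0;
      for (int k = 0; k < n_causal; ++k) {
        int a = (int)plan_allele(g, fh1, fh2, causal_chrom[k],
                                 causal_row[k], causal_idx[k]);
        w *= male_w(a, k);
      }
      if (unif_rand() >= w) continue;
    }
    materialize(g, fh1, fh2, chrom_offset, chrom_nsites, &s_h(0, s));
    ++s;
  }

  return List::create(_["female_h1"] = d_h1, _["female_h2"] = d_h2,
                      _["male_h"] = s_h);
}

// Recombinant gametes only (used to seed generation-0 males and in tests):
// one gamete per requested offspring from the given mothers.
// [[Rcpp::export(name = ".meiosis_gametes")]]
RawMatrix meiosis_gametes(const RawMatrix& h1, const RawMatrix& h2,
                          const IntegerVector& mothers,
                          const IntegerVector& pos,
                          const IntegerVector& chrom_offset,
                          const IntegerVector& chrom_nsites,
                          const NumericVector& chrom_len) {
  const int n_sites = h1.nrow();
  const int n_g = mothers.size();
  const int n_chrom = chrom_offset.size();
  RawMatrix out(n_sites, n_g);
  RNGScope rng;
  GametePlan g;
  g.brk.resize(n_chrom);
  g.first.resize(n_chrom);
  for (int j = 0; j < n_g; ++j) {
    g.mother = mothers[j] - 1;
    if (g.mother < 0 || g.mother >= h1.ncol()) stop("mother index out of range");
    for (int c = 0; c < n_chrom; ++c) {
      double bp = unif_rand() * chrom_len[c];
      g.brk[c] = brk_count(&pos[chrom_offset[c]], chrom_nsites[c], bp);
      g.first[c] = unif_rand() < 0.5;
    }
    materialize(g, h1, h2, chrom_offset, chrom_nsites, &out(0, j));
  }
  return out;
}
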