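regulator_id	role
SETD1A	histone_writer
SETD1B	histone_writer
KMT2A	histone_writer
KMT2B	histone_writer
KMT2C	histone_writer
KMT2D	histone_writer
KDM1A	histone_eraser
KDM1B	histone_eraser
KDM2A	histone_eraser
KDM2B	histone_eraser
KDM5A	histone_eraser
KDM5B	histone_eraser
KDM5C	histone_eraser
KDM5D	histone_eraser
CREBBP	histone_acetylase
EP300	histone_acetylase
HDAC1	histone_deacetylase
HDAC2	histone_deacetylase
HDAC3	histone_deacetylase
HDAC8	histone_deacetylase
HDAC11	histone_deacetylase
METTL14	m6a_writer
METTL3	m6a_writer
METTL16	m6a_writer
RBM15	m6a_writer
RBM15B	m6a_writer
ZC3H13	m6a_writer
ZCCHC4	m6a_writer
WTAP	m6a_writer
CBLL1	m6a_writer
VIRMA	m6a_writer
YTHDC1	m6a_reader
YTHDC2	m6a_reader
YTHDF1	m6a_reader
YTHDF2	m6a_reader
YTHDF3	m6a_reader
IGF2BP1	m6a_reader
IGF2BP2	m6a_reader
IGF2BP3	m6a_reader
HNRNPA2B1	m6a_reader
HNRNPC	m6a_reader
ALKBH5	m6a_eraser
FTO	m6a_eraser
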