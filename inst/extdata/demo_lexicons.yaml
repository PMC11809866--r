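# Synthetic demo lexicon set for the screening classifiers.
# The group layout (24 linguistic / 29 affective / 12 personal-biological /
# 10 suicide-risk / 9 eating-disorder lexicons, 84 features in total) mirrors
# the structure of clinician-curated screening feature sets; the term lists
# themselves are synthetic stand-ins (mixed Spanish/English) built for
# testing and demonstration, not a clinically validated resource.
linguistic_dimensions:
  first_person_singular: [yo, me, mi, conmigo, i, myself]
  first_person_plural: [nosotras, nosotros, nuestro, nuestra, we, us]
  second_person: [tu, usted, vos, ti, you]
  third_person: [ella, ellos, ellas, she, they, them]
  articles: [el, la, los, las, un, una]
  prepositions: [de, en, por, para, con, sin]
  conjunctions: [y, pero, aunque, porque, and, but]
  negations: [no, nunca, jamas, nada, never, not]
  auxiliaries: [ser, estar, haber, tengo, am, is]
  adverbs: [muy, siempre, casi, really, very, tan]
  quantifiers: [todo, mucho, poco, algunos, all, some]
  numbers: [uno, dos, tres, cien, mil, cero]
  interrogatives: [que, como, cuando, donde, why, how]
  past_focus: [ayer, antes, fue, era, yesterday, was]
  present_focus: [hoy, ahora, estoy, today, now]
  future_focus: [manana, luego, sera, will, tomorrow]
  comparisons: [mas, menos, mejor, peor, more, less]
  certainty: [seguro, claro, obvio, definitivamente, certainly]
  tentative: [quizas, quiza, acaso, maybe, perhaps]
  assent: [si, vale, ok, claro, yes]
  fillers: [pues, bueno, este, like, um]
  netspeak: [lol, jaja, jajaja, xd, omg, rt]
  swearing: [maldito, maldita, mierda, damn]
  exclusive: [excepto, salvo, sino, except, only]
affective_processes:
  positive_emotion: [feliz, alegre, contenta, happy, glad]
  negative_emotion: [triste, mal, horrible, awful, bad]
  anxiety: [ansiedad, ansiosa, nerviosa, anxious, nervous]
  anger: [rabia, enfado, furiosa, angry, ira]
  sadness: [tristeza, llorar, pena, sad, sadness]
  joy: [alegria, reir, disfrutar, joy, fun]
  fear: [miedo, temor, asustada, fear, afraid]
  disgust: [asco, repugnante, disgust, gross]
  shame: [verguenza, avergonzada, shame, ashamed]
  guilt: [culpa, culpable, guilt, guilty]
  loneliness: [sola, solo, soledad, lonely, alone]
  hopelessness: [desesperanza, inutil, hopeless, pointless]
  love: [amor, querer, amar, love, cariño]
  hate: [odio, odiar, hate, detesto]
  worry: [preocupada, preocupacion, worry, worried]
  stress: [estres, estresada, agobiada, stress, stressed]
  calm: [tranquila, calma, serena, calm, peaceful]
  crying: [llorando, lloro, lagrimas, crying, tears]
  despair: [desesperada, desesperacion, despair]
  envy: [envidia, celos, envy, jealous]
  frustration: [frustrada, frustracion, frustrated]
  irritability: [irritada, molesta, irritable, annoyed]
  mood_swings: [altibajos, cambios, swings, inestable]
  emptiness: [vacia, vacio, empty, hueco]
  numbness: [entumecida, insensible, numb, nothing]
  panic: [panico, crisis, panic, attack]
  relief: [alivio, aliviada, relief, relieved]
  self_criticism: [fracaso, fracasada, failure, useless, torpe]
  apathy: [apatia, desgana, apathy, whatever]
personal_concerns_biological:
  body: [cuerpo, piel, figura, body, waist, cintura]
  eating: [comer, comida, comiendo, eat, eating, meal]
  sleep: [dormir, sueño, insomnio, sleep, awake]
  health: [salud, enferma, doctor, health, sick]
  exercise: [ejercicio, correr, gimnasio, exercise, gym]
  family: [familia, madre, padre, family, mother]
  friends: [amigas, amigos, friend, friends]
  school: [clase, escuela, examen, school, class]
  work: [trabajo, oficina, jefe, work, job]
  money: [dinero, comprar, pagar, money, buy]
  death: [muerte, morir, death, die]
  medication: [pastillas, medicacion, medicina, pills, meds]
suicide_risk:
  self_harm: [autolesion, autolesiones, cortarme, harm]
  ideation: [desaparecer, rendirme, disappear, sin ganas]
  burden: [carga, estorbo, molestia, burden]
  farewell: [despedida, adios, goodbye forever, ultima vez]
  isolation: [aislada, encerrada, nadie, isolated, alone]
  hopeless_outlook: [sin salida, sin futuro, no point, sin sentido]
  sleep_disturbance: [no duermo, desvelada, madrugada, sleepless]
  psychological_pain: [dolor, sufrimiento, suffering, aguantar]
  past_attempts: [intento, recaida, otra vez, again]
  help_seeking: [ayuda, ayudenme, help me, socorro]
eating_disorder:
  restriction: [ayuno, ayunar, restriccion, fasting, restrict]
  binge: [atracon, atracones, binge, descontrol]
  purge: [purga, purgar, vomitar, purge]
  calorie_counting: [calorias, contar calorias, kcal, calories]
  thinspiration: [thinspo, delgada ideal, meta, thin]
  body_checking: [pesarme, bascula, espejo, scale, mirror]
  compensation: [compensar, laxantes, ejercicio extremo, compensate]
  ed_community: [proana, promia, edtwt, ana, mia]
  fear_foods: [engordar, grasa, fat, gorda]
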